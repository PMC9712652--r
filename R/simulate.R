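# Synthetic cohorts with known ground truth.
#
# The simulator emulates an extreme-phenotype rare-variant study: a discovery
# case cohort (default 97 whole genomes) with a labelled severe subset (34),
# an independent replication cohort (147), and an external population
# reference panel (1000 individuals) supplying allele counts. Per-gene
# enrichment is planted on the odds-ratio scale so the planted OR is exactly
# the estimand of the downstream collapsing burden test, and a recurrent
# deletion is planted in a constrained region at a configurable case/reference
# carrier frequency.

# RNG stream offsets: each generator draws from seed + offset so that any
# subset of the generators can be called in any order and still reproduce.
.SEED_PANEL <- 101L
.SEED_CONSTRAINT <- 202L
.SEED_DISCOVERY <- 303L
.SEED_REPLICATION <- 404L
.SEED_SEVERE <- 505L
.SEED_SV <- 606L
.SEED_CLINICAL <- 707L

.DURATION_LEVELS <- c("6m-3y", "3-10y", "10-20y", ">20y", "missing")
.COMORBIDITIES <- c("hearing_loss", "hyperacusis", "headache", "anxiety",
                    "depression")

#' Default severity-conditional comorbidity probabilities
#'
#' One row per comorbidity flag with the Bernoulli probability for severe and
#' non-severe cases. Defaults reproduce, in expectation, cohort-level
#' comorbidity proportions typical of severe-tinnitus case series (e.g.
#' hyperacusis in ~94% of severe vs ~56% of non-severe cases, so the pooled
#' 97-case cohort lands near 69%).
#'
#' @return A tibble with columns `feature`, `p_severe`, `p_nonsevere`.
#' @export
default_clinical_probs <- function() {
  tibble::tribble(
    ~feature,       ~p_severe, ~p_nonsevere,
    "hearing_loss", 0.79,      0.56,
    "hyperacusis",  0.94,      0.56,
    "headache",     0.32,      0.38,
    "anxiety",      0.74,      0.46,
    "depression",   0.38,      0.27
  )
}

#' Default structural-variant simulation parameters
#'
#' @return A list with the deletion/duplication counts, length range in bp,
#'   planted recurrent-deletion carrier frequencies (cases and reference),
#'   the fraction of background SVs placed over constrained genes, and the
#'   fractions used to build the matching known-SV and blacklist sets.
#' @export
default_sv_spec <- function() {
  list(
    n_del = 40L,
    n_dup = 20L,
    length_range = c(1000, 1000000),
    recurrent_case_freq = 0.216,
    recurrent_ref_freq = 0.017,
    background_freq_shape = c(0.2, 50),
    constrained_overlap_fraction = 0.3,
    known_fraction = 0.9,
    blacklist_fraction = 0.08,
    benign_fraction = 0.1
  )
}

#' Simulation configuration
#'
#' Assembles and validates all parameters of the synthetic study. Defaults
#' mirror the study design the package targets: 97 discovery cases with a
#' 34-case severe subset, 147 replication cases, one 1000-sample reference
#' panel, and reference minor-allele frequencies drawn from a Beta(0.2, 50)
#' law (median well below 1%, so rare variants dominate).
#'
#' @param n_cases Discovery cohort size.
#' @param n_severe Size of the severe subset (must not exceed `n_cases`).
#' @param n_replication Replication cohort size.
#' @param n_reference Named integer vector of reference panel sizes; names are
#'   the panel labels used in column names (`ac_<panel>`, `an_<panel>`).
#' @param n_genes,variants_per_gene Gene count and sites simulated per gene.
#' @param maf_distribution Two Beta shape parameters for reference allele
#'   frequencies.
#' @param enriched_genes Tibble with columns `gene`, `target_or`,
#'   `variant_class` ("LOF" or "MISSENSE") naming genes with planted
#'   case enrichment; `NULL` for a null simulation.
#' @param constrained_fraction Fraction of genes flagged high-constraint
#'   (pLI > 0.9, LOEUF < 0.5, LOEUF bin < 2). Enriched genes are always
#'   included in the constrained set.
#' @param sv_spec Structural-variant parameters, see [default_sv_spec()].
#' @param clinical_probs Comorbidity probabilities, see
#'   [default_clinical_probs()].
#' @param duration_probs Probabilities over the five tinnitus-duration
#'   categories (6m-3y, 3-10y, 10-20y, >20y, missing).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   outputs.
#' @return A validated `sim_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 5, variants_per_gene = 4, seed = 1)
#' panel <- simulate_reference_panel(cfg)
simulation_config <- function(n_cases = 97,
                              n_severe = 34,
                              n_replication = 147,
                              n_reference = c(panel1 = 1000),
                              n_genes = 50,
                              variants_per_gene = 8,
                              maf_distribution = c(0.2, 50),
                              enriched_genes = NULL,
                              constrained_fraction = 0.3,
                              sv_spec = default_sv_spec(),
                              clinical_probs = default_clinical_probs(),
                              duration_probs = c(0.17, 0.22, 0.35, 0.18, 0.08),
                              seed = 20201) {
  for (nm in c("n_cases", "n_severe", "n_replication", "n_genes",
               "variants_per_gene")) {
    if (!is_count(get(nm))) {
      abort_config(sprintf("`%s` must be a single positive integer.", nm))
    }
  }
  if (n_severe > n_cases) {
    abort_config("`n_severe` must not exceed `n_cases`.")
  }
  if (length(n_reference) < 1 || is.null(names(n_reference)) ||
      any(!nzchar(names(n_reference))) || any(n_reference < 1)) {
    abort_config("`n_reference` must be a named vector of positive panel sizes.")
  }
  if (length(maf_distribution) != 2 || any(!is.finite(maf_distribution)) ||
      any(maf_distribution <= 0)) {
    abort_config("`maf_distribution` must be two positive Beta shape parameters.")
  }
  if (!is.null(enriched_genes)) {
    enriched_genes <- tibble::as_tibble(enriched_genes)
    req <- c("gene", "target_or", "variant_class")
    if (!all(req %in% names(enriched_genes))) {
      abort_config("`enriched_genes` needs columns gene, target_or, variant_class.")
    }
    if (any(enriched_genes$target_or <= 0)) {
      abort_config("Target odds ratios must be > 0.")
    }
    if (!all(enriched_genes$variant_class %in% c("LOF", "MISSENSE"))) {
      abort_config("Planted `variant_class` must be LOF or MISSENSE.")
    }
  }
  if (!is_prob(constrained_fraction) || length(constrained_fraction) != 1) {
    abort_config("`constrained_fraction` must be a probability.")
  }
  sv_spec <- utils::modifyList(default_sv_spec(), sv_spec)
  if (sv_spec$length_range[1] >= sv_spec$length_range[2]) {
    abort_config("`sv_spec$length_range` must be increasing (min < max).")
  }
  if (!is_prob(c(sv_spec$recurrent_case_freq, sv_spec$recurrent_ref_freq,
                 sv_spec$constrained_overlap_fraction, sv_spec$known_fraction,
                 sv_spec$blacklist_fraction, sv_spec$benign_fraction))) {
    abort_config("sv_spec frequencies and fractions must lie in [0, 1].")
  }
  clinical_probs <- tibble::as_tibble(clinical_probs)
  if (!all(c("feature", "p_severe", "p_nonsevere") %in% names(clinical_probs)) ||
      !is_prob(clinical_probs$p_severe) || !is_prob(clinical_probs$p_nonsevere)) {
    abort_config("`clinical_probs` needs feature, p_severe, p_nonsevere in [0, 1].")
  }
  if (length(duration_probs) != 5 || !is_prob(duration_probs)) {
    abort_config("`duration_probs` must be five probabilities.")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      abs(seed) > 2^31 - 1e4) {
    abort_config("`seed` must be a single integer below 2^31.")
  }
  structure(
    list(
      n_cases = as.integer(n_cases), n_severe = as.integer(n_severe),
      n_replication = as.integer(n_replication),
      n_reference = setNames(as.integer(n_reference), names(n_reference)),
      n_genes = as.integer(n_genes),
      variants_per_gene = as.integer(variants_per_gene),
      maf_distribution = as.numeric(maf_distribution),
      enriched_genes = enriched_genes,
      constrained_fraction = constrained_fraction,
      sv_spec = sv_spec,
      clinical_probs = clinical_probs,
      duration_probs = duration_probs / sum(duration_probs),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

sim_gene_symbols <- function(config) {
  sprintf("GENE%04d", seq_len(config$n_genes))
}

#' Simulated gene intervals on the pseudo-chromosome
#'
#' Genes are tiled at fixed 100 kb offsets on a single pseudo-chromosome
#' (`chrS`), each spanning 10 kb, so interval arithmetic is exercised without
#' a genome build. Coordinates are 0-based half-open.
#'
#' @param config A [simulation_config()].
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
sim_gene_intervals <- function(config) {
  i <- seq_len(config$n_genes)
  tibble::tibble(
    gene = sim_gene_symbols(config),
    chrom = "chrS",
    start = (i - 1L) * 100000L,
    end = (i - 1L) * 100000L + 10000L
  )
}

case_sample_ids <- function(n, prefix = "CASE") {
  sprintf("%s%04d", prefix, seq_len(n))
}

# Severe subset is drawn once from its own RNG stream so the case cohort,
# SV call set and clinical table all agree on which samples are severe.
severe_sample_ids <- function(config, prefix = "CASE") {
  ids <- case_sample_ids(config$n_cases, prefix)
  with_seed(config$seed + .SEED_SEVERE,
            sort(sample(ids, config$n_severe)))
}

# Consequence terms drawn per site; enriched genes get all sites in their
# planted class so the gene-level collapsed frequency is the planted one.
.CSQ_TERMS <- c(
  missense_variant = 0.40, synonymous_variant = 0.25,
  inframe_deletion = 0.10, `5_prime_UTR_variant` = 0.11,
  stop_gained = 0.04, frameshift_variant = 0.04,
  splice_donor_variant = 0.02, splice_acceptor_variant = 0.02,
  stop_lost = 0.01, start_lost = 0.01
)
.LOF_TERMS <- c("stop_gained", "stop_lost", "start_lost", "frameshift_variant",
                "splice_donor_variant", "splice_acceptor_variant")

#' Generate the reference frequency panel(s)
#'
#' Draws one latent allele frequency per simulated site from the configured
#' Beta law, then realizes per-panel allele counts binomially at panel size.
#' Under the default Beta(0.2, 50) most sites have frequency below 1%
#' (the rare-variant regime).
#'
#' @param config A [simulation_config()].
#' @return A tibble, one row per site and panel, with columns `panel`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `gene`, `consequence`, `cadd`,
#'   `ac`, `an` (= 2 x panel size), `freq` and the latent `true_freq` used
#'   for sampling (kept for ground-truth checks; a real panel has no such
#'   column).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_symbols(config)
  gi <- sim_gene_intervals(config)
  v <- config$variants_per_gene
  nv <- config$n_genes * v

  with_seed(config$seed + .SEED_PANEL, {
    sites <- tibble::tibble(
      gene = rep(genes, each = v),
      chrom = "chrS",
      pos = rep(gi$start, each = v) + 1L + (rep(seq_len(v), config$n_genes) - 1L) * 10L,
      ref = sample(c("A", "C", "G", "T"), nv, replace = TRUE),
      consequence = sample(names(.CSQ_TERMS), nv, replace = TRUE,
                           prob = .CSQ_TERMS),
      cadd = round(pmax(0.1, rnorm(nv, 15, 8)), 1),
      true_freq = rbeta(nv, config$maf_distribution[1], config$maf_distribution[2])
    )
    sites$alt <- vapply(sites$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1), USE.NAMES = FALSE)
    sites$cadd[runif(nv) < 0.02] <- NA_real_

    if (!is.null(config$enriched_genes)) {
      for (k in seq_len(nrow(config$enriched_genes))) {
        g <- config$enriched_genes$gene[k]
        cls <- config$enriched_genes$variant_class[k]
        idx <- which(sites$gene == g)
        if (length(idx) == 0) {
          abort_config(sprintf("Enriched gene %s is not among simulated genes.", g))
        }
        sites$consequence[idx] <- if (cls == "LOF") {
          sample(.LOF_TERMS, length(idx), replace = TRUE)
        } else {
          "missense_variant"
        }
        sites$cadd[idx] <- round(runif(length(idx), 21, 40), 1)
        # Planted genes carry several individually-rare sites whose collapsed
        # reference frequency clears the 1% collapsing regime: per-site
        # frequencies uniform in [1.5e-3, 5e-3], so every site stays safely
        # below the rarity cutoff while the gene-level collapsed frequency
        # lands in ~0.012-0.04 (for the default eight sites per gene). This
        # keeps the planted odds ratio the estimand of the downstream test
        # instead of being eroded by rarity filtering of common sites.
        sites$true_freq[idx] <- runif(length(idx), 0.0015, 0.005)
      }
    }

    purrr::imap_dfr(config$n_reference, function(np, panel_name) {
      an <- 2L * np
      ac <- rbinom(nv, an, sites$true_freq)
      dplyr::mutate(sites, panel = panel_name, ac = ac, an = an,
                    freq = ac / an, .before = 1)
    })
  })
}

# Per-site case allele frequencies with planted gene-level enrichment.
# The odds-ratio identity f_case = OR f / (1 - f + OR f) is applied to the
# gene's collapsed (summed) latent frequency, then spread proportionally over
# the gene's sites, so the planted OR is the estimand of the collapsing test.
planted_case_freqs <- function(config, sites) {
  f <- sites$true_freq
  if (is.null(config$enriched_genes)) {
    return(f)
  }
  for (k in seq_len(nrow(config$enriched_genes))) {
    g <- config$enriched_genes$gene[k]
    or <- config$enriched_genes$target_or[k]
    idx <- which(sites$gene == g)
    f_gene <- sum(sites$true_freq[idx])
    if (f_gene >= 1) {
      abort_config(sprintf(
        "Collapsed reference frequency of %s is %.3f >= 1; cannot plant an odds ratio.",
        g, f_gene))
    }
    f_case_gene <- or * f_gene / (1 - f_gene + or * f_gene)
    f[idx] <- sites$true_freq[idx] * (f_case_gene / f_gene)
    if (any(f[idx] > 1)) {
      abort_config(sprintf(
        "Target odds ratio %.2f for %s implies a per-site case frequency > 1.",
        or, g))
    }
  }
  f
}

#' Generate a diploid case cohort with planted per-gene enrichment
#'
#' Genotypes are sampled per allele under Hardy-Weinberg independence at the
#' sites defined by the reference panel. For genes without planted enrichment
#' the case allele frequency equals the panel's latent frequency in
#' expectation; for planted genes the gene-level collapsed case/reference
#' allele odds match the configured odds ratio in expectation.
#'
#' @param config A [simulation_config()].
#' @param panel Output of [simulate_reference_panel()] built from the same
#'   config.
#' @param cohort `"discovery"` (size `n_cases`, with a labelled severe
#'   subset) or `"replication"` (size `n_replication`).
#' @return A list with `variants` (tibble: site annotations, `ac_case`,
#'   `an_case`, per-panel `ac_<panel>`/`an_<panel>` columns, and a `gt`
#'   list-column of per-sample allele dosages), `samples` (tibble with
#'   `sample_id` and, for discovery, the `severe` flag), and `truth`
#'   (per-gene enrichment ground truth, one row per simulated gene).
#' @export
simulate_case_cohort <- function(config, panel,
                                 cohort = c("discovery", "replication")) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- match.arg(cohort)
  n <- if (cohort == "discovery") config$n_cases else config$n_replication
  prefix <- if (cohort == "discovery") "CASE" else "REPL"
  offset <- if (cohort == "discovery") .SEED_DISCOVERY else .SEED_REPLICATION

  sites <- panel |>
    dplyr::select(-"panel", -"ac", -"an", -"freq") |>
    dplyr::distinct()
  wide <- panel |>
    dplyr::select("panel", "chrom", "pos", "ref", "alt", "ac", "an") |>
    tidyr::pivot_wider(names_from = "panel", values_from = c("ac", "an"),
                       names_glue = "{.value}_{panel}")
  sites <- dplyr::left_join(sites, wide, by = c("chrom", "pos", "ref", "alt"))

  f_case <- planted_case_freqs(config, sites)
  nv <- nrow(sites)
  ids <- case_sample_ids(n, prefix)

  dosage <- with_seed(config$seed + offset, {
    matrix(rbinom(nv * n, 2L, f_case), nrow = nv, dimnames = list(NULL, ids))
  })

  variants <- sites |>
    dplyr::mutate(
      ac_case = as.integer(rowSums(dosage)),
      an_case = 2L * n,
      gt = lapply(seq_len(nv), function(i) dosage[i, ])
    ) |>
    dplyr::relocate("chrom", "pos", "ref", "alt", "gene", "consequence",
                    "cadd")

  samples <- tibble::tibble(sample_id = ids)
  if (cohort == "discovery") {
    samples$severe <- samples$sample_id %in% severe_sample_ids(config, prefix)
  }

  truth <- sites |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(collapsed_ref_freq = sum(.data$true_freq),
                     .groups = "drop")
  if (is.null(config$enriched_genes)) {
    truth <- dplyr::mutate(truth, enriched = FALSE, target_or = 1,
                           variant_class = NA_character_)
  } else {
    truth <- truth |>
      dplyr::left_join(config$enriched_genes, by = "gene") |>
      dplyr::mutate(enriched = !is.na(.data$target_or),
                    target_or = dplyr::coalesce(.data$target_or, 1))
  }

  list(variants = variants, samples = samples, truth = truth)
}

#' Restrict a cohort's variant table to a subset of samples
#'
#' Recomputes case allele counts from the genotype list-column; used to run
#' the severe subset through the same burden machinery as the full cohort.
#'
#' @param variants Variant tibble with a `gt` list-column.
#' @param sample_ids Character vector of samples to keep.
#' @return The variant tibble restricted to `sample_ids`.
#' @export
subset_samples <- function(variants, sample_ids) {
  if (!"gt" %in% names(variants)) {
    abort_validation("`variants` must carry a `gt` genotype list-column.")
  }
  missing <- setdiff(sample_ids, names(variants$gt[[1]]))
  if (length(missing) > 0) {
    abort_validation(sprintf("Samples not in cohort: %s",
                             paste(missing, collapse = ", ")))
  }
  gt <- lapply(variants$gt, function(g) g[sample_ids])
  dplyr::mutate(variants,
                gt = gt,
                ac_case = vapply(gt, function(g) as.integer(sum(g, na.rm = TRUE)),
                                 integer(1)),
                an_case = 2L * length(sample_ids))
}

#' Generate the gene constraint table
#'
#' High-constraint genes (a configured fraction, always including any planted
#' enriched genes) receive pLI > 0.9, LOEUF < 0.5 and LOEUF decile bin 0-1;
#' the remainder receive tolerant scores (bins 2-9, with occasional missing
#' bins).
#'
#' @param config A [simulation_config()].
#' @return Tibble with columns `gene`, `pli`, `loeuf`, `loeuf_bin`.
#' @export
simulate_gene_constraint <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_symbols(config)
  with_seed(config$seed + .SEED_CONSTRAINT, {
    n_con <- round(config$constrained_fraction * config$n_genes)
    constrained <- union(
      if (is.null(config$enriched_genes)) character(0) else config$enriched_genes$gene,
      sample(genes, n_con)
    )
    is_con <- genes %in% constrained
    n <- length(genes)
    tibble::tibble(
      gene = genes,
      pli = ifelse(is_con, runif(n, 0.905, 1), runif(n, 0, 0.85)),
      loeuf = ifelse(is_con, runif(n, 0.05, 0.45), runif(n, 0.55, 1.9)),
      loeuf_bin = ifelse(is_con, sample(0:1, n, replace = TRUE),
                         sample(2:9, n, replace = TRUE)),
      ) |>
      dplyr::mutate(loeuf_bin = replace(.data$loeuf_bin,
                                        !is_con & runif(n) < 0.05,
                                        NA_integer_))
  })
}

#' Generate a structural-variant call set with a planted recurrent deletion
#'
#' Emits DEL/DUP calls on the pseudo-chromosome with per-cohort carrier
#' counts, alongside the region sets (blacklist, constrained regions), a
#' matching known-SV set, and ground truth. One deletion is planted inside a
#' constrained gene at the configured case and reference carrier frequencies
#' (defaults 0.216 vs 0.017, the regime of a strongly enriched recurrent
#' deletion); severe-subset carriers are the planted carriers that fall in
#' the severe subsample, so the three cohort counts are mutually consistent.
#'
#' @param config A [simulation_config()].
#' @return A list: `svs` (call tibble with evidence flags and
#'   `carriers_cases`/`carriers_severe`/`carriers_reference` columns),
#'   `cohort_sizes` (named vector), `regions` (list of blacklist and
#'   constrained-region tibbles), `known` (known-SV set), `gene_intervals`,
#'   `constraint`, and `truth` (per-SV planted/constrained/ultra-rare flags).
#' @export
simulate_sv_callset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$sv_spec
  gi <- sim_gene_intervals(config)
  constraint <- simulate_gene_constraint(config)
  con_genes <- constraint$gene[constraint$pli > 0.9 & constraint$loeuf_bin < 2 &
                                 !is.na(constraint$loeuf_bin)]
  con_iv <- gi[gi$gene %in% con_genes, ]
  severe_idx <- which(case_sample_ids(config$n_cases) %in%
                        severe_sample_ids(config))
  ref_name <- names(config$n_reference)[1]
  n_ref <- config$n_reference[[1]]

  with_seed(config$seed + .SEED_SV, {
    n_sv <- spec$n_del + spec$n_dup
    if (n_sv < 1) abort_config("sv_spec needs at least one SV.")
    if (spec$constrained_overlap_fraction > 0 && nrow(con_iv) == 0) {
      abort_config("No constrained genes available to place SVs over.")
    }
    lr <- spec$length_range
    lens <- round(exp(runif(n_sv, log(lr[1]), log(lr[2]))))
    lens <- pmin(pmax(lens, lr[1]), lr[2])

    # Planted recurrent deletion sits inside the first constrained gene
    # (unless constrained overlap is disabled, in which case it is placed
    # intergenic like the background calls).
    plant_con <- spec$constrained_overlap_fraction > 0
    lens[1] <- min(max(1650, lr[1]), lr[2], 8000)
    start <- integer(n_sv)
    genome_end <- max(gi$end) + 200000L

    in_con <- c(plant_con, runif(n_sv - 1) < spec$constrained_overlap_fraction)
    # constrained calls start inside a constrained gene body; the rest are
    # placed beyond the gene tiling (calls can span up to 1 Mb, so placing
    # them between tiles would drag them across constrained genes)
    for (i in seq_len(n_sv)) {
      if (in_con[i]) {
        g <- con_iv[sample(nrow(con_iv), 1), ]
        start[i] <- as.integer(g$start + sample(0:8000, 1))
      } else {
        start[i] <- as.integer(genome_end + 1100000 * i + sample(0:50000, 1))
      }
    }
    if (plant_con) start[1] <- con_iv$start[1] + 1000L
    end <- as.integer(start + lens)
    sv_type <- c("DEL", rep(c("DEL", "DUP"),
                            times = c(spec$n_del - 1L, spec$n_dup)))

    latent <- rbeta(n_sv, spec$background_freq_shape[1],
                    spec$background_freq_shape[2])
    case_freq <- latent
    ref_freq <- latent
    case_freq[1] <- spec$recurrent_case_freq
    ref_freq[1] <- spec$recurrent_ref_freq

    carrier_mat <- matrix(runif(n_sv * config$n_cases) < case_freq,
                          nrow = n_sv)
    carriers_cases <- as.integer(rowSums(carrier_mat))
    carriers_severe <- as.integer(rowSums(carrier_mat[, severe_idx,
                                                      drop = FALSE]))
    carriers_reference <- rbinom(n_sv, n_ref, ref_freq)

    benign <- runif(n_sv) < spec$benign_fraction
    benign[1] <- FALSE

    svs <- tibble::tibble(
      sv_id = sprintf("SV%03d", seq_len(n_sv)),
      chrom = "chrS", start = start, end = end, sv_type = sv_type,
      carriers_cases = carriers_cases,
      carriers_severe = carriers_severe,
      carriers_reference = carriers_reference,
      benign_overlap = benign,
      dosage_sensitive_loss = FALSE
    )

    known_idx <- sort(unique(c(1L, which(runif(n_sv) < spec$known_fraction))))
    known <- svs[known_idx, c("chrom", "start", "end", "sv_type")]
    # jitter the known coordinates by <0.3% of length: reciprocal overlap
    # stays above the 99% concordance threshold
    jit <- pmax(0L, as.integer(floor((known$end - known$start) * 0.002)))
    known$start <- known$start + jit

    bl_idx <- which(!in_con & runif(n_sv) < spec$blacklist_fraction &
                      seq_len(n_sv) != 1L)
    blacklist <- tibble::tibble(
      chrom = "chrS",
      start = as.integer(svs$start[bl_idx]),
      end = as.integer(svs$start[bl_idx] +
                         ceiling(0.8 * (svs$end[bl_idx] - svs$start[bl_idx])))
    )
    # plus background junk intervals far beyond the gene tiling
    blacklist <- dplyr::bind_rows(blacklist, tibble::tibble(
      chrom = "chrS",
      start = as.integer(genome_end + c(0L, 50000L)),
      end = as.integer(genome_end + c(20000L, 90000L))
    ))

    regions <- list(
      blacklist = blacklist,
      constrained = tibble::tibble(chrom = con_iv$chrom,
                                   start = con_iv$start, end = con_iv$end)
    )

    truth <- tibble::tibble(
      sv_id = svs$sv_id,
      planted = seq_len(n_sv) == 1L,
      constrained_true = in_con,
      ultra_rare_true = carriers_reference / n_ref <= 0.001,
      known_true = seq_len(n_sv) %in% known_idx,
      blacklisted_true = seq_len(n_sv) %in% bl_idx
    )

    list(
      svs = svs,
      cohort_sizes = c(cases = config$n_cases, severe = config$n_severe,
                       reference = n_ref),
      reference_name = ref_name,
      regions = regions,
      known = known,
      gene_intervals = gi,
      constraint = constraint,
      truth = truth
    )
  })
}

#' Generate the clinical table for the discovery cohort
#'
#' One record per case. Severe cases (the same subsample labelled by
#' [simulate_case_cohort()]) draw THI scores in 58-100, non-severe in 0-57;
#' every case draws TFI >= 48 (the chronic-inclusion regime); comorbidity
#' flags are Bernoulli with severity-conditional probabilities.
#'
#' @param config A [simulation_config()].
#' @return Tibble with one row per case: `subject_id`, `age`, `sex`, `thi`,
#'   `tfi`, the five comorbidity flags, `duration_category`, `severe`.
#' @export
simulate_clinical_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- case_sample_ids(config$n_cases)
  severe <- ids %in% severe_sample_ids(config)
  n <- config$n_cases
  with_seed(config$seed + .SEED_CLINICAL, {
    rec <- tibble::tibble(
      subject_id = ids,
      age = pmin(pmax(round(rnorm(n, 46, 13)), 18), 85),
      sex = sample(c("female", "male"), n, replace = TRUE,
                   prob = c(0.56, 0.44)),
      thi = ifelse(severe, sample(58:100, n, replace = TRUE),
                   sample(0:57, n, replace = TRUE)),
      tfi = sample(48:100, n, replace = TRUE),
      duration_category = sample(.DURATION_LEVELS, n, replace = TRUE,
                                 prob = config$duration_probs),
      severe = severe
    )
    for (k in seq_len(nrow(config$clinical_probs))) {
      p <- config$clinical_probs[k, ]
      rec[[p$feature]] <- runif(n) < ifelse(severe, p$p_severe, p$p_nonsevere)
    }
    dplyr::relocate(rec, dplyr::any_of(.COMORBIDITIES), .after = "tfi")
  })
}
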