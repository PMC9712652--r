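# Structural-variant prioritization and carrier-frequency burden.
#
# Filtering stages, in pipeline order (each a pure predicate, so the order is
# also the joint filter): size window (1 kb - 1 Mb inclusive; oversized calls
# survive only with >= 99% known-SV concordance), blacklist-artifact removal
# (dropped iff strictly more than 66% of the call is covered by blacklist
# regions -- one-sided coverage of the SV), known-SV concordance (kept iff
# reciprocal overlap >= 99% with a same-type known call), simplified
# ACMG-style classification (classes 3-5 retained), constrained-region
# overlap (pLI > 0.9 and LOEUF bin < 2), ultra-rare flagging (reference
# carrier frequency <= 0.001, the resolution of a 1000-sample panel), and a
# per-SV carrier 2x2 chi-squared burden against the reference cohort.

sv_length <- function(svs) svs$end - svs$start

#' Partition structural variants by the size window
#'
#' @param svs SV tibble (`chrom`, `start`, `end` 0-based half-open, `sv_type`).
#' @param min_bp,max_bp Inclusive window bounds (defaults 1 kb and 1 Mb).
#' @return List with `kept` (length inside the window) and `oversized`
#'   (length above `max_bp`; these survive downstream only if they pass the
#'   known-SV concordance filter). Undersized calls are dropped outright.
#' @export
sv_filter_size <- function(svs, min_bp = 1000, max_bp = 1000000) {
  if (min_bp >= max_bp) abort_config("`min_bp` must be below `max_bp`.")
  len <- sv_length(svs)
  list(kept = svs[len >= min_bp & len <= max_bp, , drop = FALSE],
       oversized = svs[len > max_bp, , drop = FALSE])
}

# Reduced (merged) IRanges per chromosome for a region tibble.
regions_by_chrom <- function(regions) {
  split(IRanges::IRanges(start = regions$start + 1L, end = regions$end),
        regions$chrom) |>
    lapply(IRanges::reduce)
}

#' Fraction of each SV covered by a region set
#'
#' Computes, per SV, the length of the intersection between the SV and the
#' union of the regions, divided by the SV length. Using the union means
#' overlapping or fragmented regions are never double-counted, so the value
#' is invariant under splitting a region into adjacent pieces.
#'
#' @param svs SV tibble (0-based half-open coordinates).
#' @param regions Region tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @return Numeric vector in `[0, 1]`, one value per SV.
#' @export
covered_fraction <- function(svs, regions) {
  if (nrow(svs) == 0) return(numeric(0))
  if (nrow(regions) == 0) return(rep(0, nrow(svs)))
  reduced <- regions_by_chrom(regions)
  vapply(seq_len(nrow(svs)), function(i) {
    r <- reduced[[svs$chrom[i]]]
    if (is.null(r)) return(0)
    iv <- IRanges::IRanges(start = svs$start[i] + 1L, end = svs$end[i])
    sum(IRanges::width(IRanges::intersect(iv, r))) / (svs$end[i] - svs$start[i])
  }, numeric(1))
}

#' Remove likely-artifactual calls overlapping blacklist regions
#'
#' Drops an SV iff strictly more than `threshold` of its length is covered by
#' the blacklist (genome gaps, segmental duplications, V(D)J regions);
#' coverage of exactly the threshold is kept.
#'
#' @param svs SV tibble.
#' @param blacklist Region tibble.
#' @param threshold Coverage threshold, default 0.66.
#' @return The retained SV tibble, with a `blacklist_fraction` column.
#' @export
sv_filter_artifacts <- function(svs, blacklist, threshold = 0.66) {
  frac <- covered_fraction(svs, blacklist)
  out <- dplyr::mutate(svs, blacklist_fraction = frac)
  out[frac <= threshold, , drop = FALSE]
}

#' Reciprocal overlap between two intervals
#'
#' Intersection length divided by the length of the longer interval;
#' symmetric in its arguments. Vectorized; coordinates 0-based half-open.
#'
#' @param a_start,a_end,b_start,b_end Interval coordinates.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' reciprocal_overlap(0, 1000, 0, 990) # 0.99
reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  inter / pmax(a_end - a_start, b_end - b_start)
}

# Best reciprocal overlap of each SV against same-chromosome, same-type
# known calls.
best_reciprocal <- function(svs, known) {
  if (nrow(svs) == 0) return(numeric(0))
  vapply(seq_len(nrow(svs)), function(i) {
    k <- known[known$chrom == svs$chrom[i] & known$sv_type == svs$sv_type[i], ]
    if (nrow(k) == 0) return(0)
    max(reciprocal_overlap(svs$start[i], svs$end[i], k$start, k$end))
  }, numeric(1))
}

#' Keep SV calls concordant with a known-SV database
#'
#' An SV is kept iff some known call of the same type on the same chromosome
#' has reciprocal overlap at or above the threshold (default 99%, inclusive),
#' filtering novel calls not reported in any database.
#'
#' @param svs SV tibble.
#' @param known Known-SV tibble (`chrom`, `start`, `end`, `sv_type`).
#' @param threshold Reciprocal-overlap threshold, default 0.99.
#' @return The retained SV tibble with a `best_reciprocal` column.
#' @export
sv_filter_known <- function(svs, known, threshold = 0.99) {
  br <- best_reciprocal(svs, known)
  out <- dplyr::mutate(svs, best_reciprocal = br)
  out[br >= threshold, , drop = FALSE]
}

#' Default ACMG-style classification rubric
#'
#' A deliberately small, declarative stand-in for dosage-sensitivity scoring:
#' ordered rules mapping evidence flags (logical columns of the SV table) to
#' classes 1-5; the first matching rule wins and SVs matching no rule get the
#' default class 2 (likely benign). Benign-region overlap outranks everything
#' (class 2); documented dosage-sensitive gene loss gives class 4 (likely
#' pathogenic); bare constrained-gene overlap gives class 3 (uncertain
#' significance).
#'
#' @return Tibble with columns `evidence` and `class`, plus a
#'   `default_class` attribute.
#' @export
acmg_default_rules <- function() {
  structure(
    tibble::tribble(
      ~evidence,               ~class,
      "benign_overlap",         2L,
      "dosage_sensitive_loss",  4L,
      "constrained_gene_overlap", 3L
    ),
    default_class = 2L
  )
}

#' Assign simplified ACMG-style classes to SV calls
#'
#' @param svs SV tibble whose logical evidence columns are named by the rules.
#' @param rules Rubric tibble as from [acmg_default_rules()]; every
#'   `evidence` entry must name a column of `svs`.
#' @return `svs` with an `acmg_class` integer column (1-5).
#' @export
sv_classify_acmg <- function(svs, rules = acmg_default_rules()) {
  missing <- setdiff(rules$evidence, names(svs))
  if (length(missing) > 0) {
    abort_config(sprintf("Evidence key(s) absent from the SV table: %s",
                         paste(missing, collapse = ", ")))
  }
  cls <- rep(attr(rules, "default_class") %||% 2L, nrow(svs))
  assigned <- rep(FALSE, nrow(svs))
  for (k in seq_len(nrow(rules))) {
    flag <- svs[[rules$evidence[k]]]
    hit <- !assigned & !is.na(flag) & flag
    cls[hit] <- rules$class[k]
    assigned <- assigned | hit
  }
  dplyr::mutate(svs, acmg_class = as.integer(cls))
}

#' Keep reportable SV calls (ACMG classes 3-5)
#'
#' Classes 3, 4 and 5 (uncertain significance, likely pathogenic, pathogenic)
#' are retained for burden analysis; benign and likely benign calls are
#' dropped.
#'
#' @param svs SV tibble with an `acmg_class` column.
#' @return The retained SV tibble.
#' @export
retain_reportable <- function(svs) {
  if (!"acmg_class" %in% names(svs)) {
    abort_validation("`svs` has no `acmg_class` column; run sv_classify_acmg() first.")
  }
  svs[svs$acmg_class %in% 3:5, , drop = FALSE]
}

#' Flag SVs overlapping constrained genes
#'
#' An SV is constrained iff it intersects at least one gene with pLI > 0.9
#' and LOEUF decile bin < 2 (both strict; a missing bin never qualifies).
#'
#' @param svs SV tibble.
#' @param gene_intervals Tibble `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param constraint Constraint tibble (`gene`, `pli`, `loeuf_bin`).
#' @return `svs` with `constrained` (logical) and `constrained_genes`
#'   (comma-separated symbols, `""` when none).
#' @export
sv_constrained_overlap <- function(svs, gene_intervals, constraint) {
  con <- constraint[!is.na(constraint$loeuf_bin) & constraint$pli > 0.9 &
                      constraint$loeuf_bin < 2, ]
  gi <- gene_intervals[gene_intervals$gene %in% con$gene, , drop = FALSE]
  genes <- vapply(seq_len(nrow(svs)), function(i) {
    g <- gi[gi$chrom == svs$chrom[i] & gi$start < svs$end[i] &
              gi$end > svs$start[i], ]
    paste(sort(g$gene), collapse = ",")
  }, character(1))
  dplyr::mutate(svs, constrained = nzchar(genes), constrained_genes = genes)
}

#' Flag ultra-rare SVs against the reference panel
#'
#' Ultra-rare iff the reference carrier frequency is at or below
#' `max_ref_freq` (default 0.001, the frequency resolution of a 1000-sample
#' panel, boundary inclusive); SVs absent from the reference count as
#' frequency 0.
#'
#' @param svs SV tibble with a `carriers_<reference>` column.
#' @param reference Reference cohort name.
#' @param cohort_sizes Named vector of cohort sizes.
#' @param max_ref_freq Frequency cutoff.
#' @return `svs` with an `ultra_rare` logical column.
#' @export
sv_flag_ultra_rare <- function(svs, reference, cohort_sizes,
                               max_ref_freq = 0.001) {
  if (!reference %in% names(cohort_sizes)) {
    abort_validation(sprintf("No cohort size for `%s`.", reference))
  }
  n_ref <- cohort_sizes[[reference]]
  col <- paste0("carriers_", reference)
  carriers <- if (col %in% names(svs)) dplyr::coalesce(svs[[col]], 0L) else 0L
  dplyr::mutate(svs, ultra_rare = carriers / n_ref <= max_ref_freq)
}

#' Carrier-frequency burden test for structural variants
#'
#' Per SV (or per DEL/DUP x constraint group), builds the carrier 2x2 table
#' (carriers vs non-carriers in the case cohort and in the reference) and
#' tests it with the same Pearson chi-squared construction as the gene
#' burden ([burden_test()] in carrier mode). A table with no carriers in
#' either cohort is degenerate and reported with p = 1 and a missing OR.
#'
#' @param svs SV tibble with `carriers_<cohort>` columns (and optionally
#'   `constrained_genes`, `ultra_rare`, `constrained`, `acmg_class` columns,
#'   which are carried through).
#' @param case,reference Cohort names for the comparison.
#' @param cohort_sizes Named vector of cohort sample counts.
#' @param grouping `"none"` (per SV, default) or `"type_constraint"`
#'   (clustered by DEL/DUP and constrained flag).
#' @param alpha Significance level for the `enriched` flag.
#' @return An `sv_burden` tibble sorted by p then OR, with carrier counts,
#'   frequencies (3 decimals), chi2, p and flags.
#' @export
sv_burden <- function(svs, case, reference, cohort_sizes,
                      grouping = c("none", "type_constraint"), alpha = 0.05) {
  grouping <- match.arg(grouping)
  for (nm in c(case, reference)) {
    if (!nm %in% names(cohort_sizes)) {
      abort_validation(sprintf("Missing cohort size for `%s`.", nm))
    }
  }
  case_col <- paste0("carriers_", case)
  ref_col <- paste0("carriers_", reference)
  if (!all(c(case_col, ref_col) %in% names(svs))) {
    abort_validation("Carrier-count columns missing for the requested cohorts.")
  }
  n_case <- cohort_sizes[[case]]
  n_ref <- cohort_sizes[[reference]]
  if (any(svs[[case_col]] > n_case) || any(svs[[ref_col]] > n_ref)) {
    abort_validation("Carrier counts exceed the declared cohort size.")
  }

  if (grouping == "type_constraint") {
    if (!"constrained" %in% names(svs)) {
      abort_validation("`type_constraint` grouping needs a `constrained` column.")
    }
    tab <- svs |>
      dplyr::group_by(.data$sv_type, .data$constrained) |>
      dplyr::summarise(
        sv_id = paste0(.data$sv_type[1], ifelse(.data$constrained[1],
                                                "_constrained", "_other")),
        n_svs = dplyr::n(),
        case_carriers = sum(.data[[case_col]]),
        ref_carriers = sum(.data[[ref_col]]),
        .groups = "drop"
      )
    # pooled carrier counts can exceed the cohort size; cap at the number of
    # distinct samples for the 2x2 (a sample carrying two grouped SVs is one
    # carrier at most)
    tab$case_carriers <- pmin(tab$case_carriers, n_case)
    tab$ref_carriers <- pmin(tab$ref_carriers, n_ref)
  } else {
    tab <- dplyr::transmute(svs,
      sv_id = .data$sv_id, sv_type = .data$sv_type,
      genes = if ("constrained_genes" %in% names(svs)) .data$constrained_genes else NA_character_,
      case_carriers = .data[[case_col]],
      ref_carriers = .data[[ref_col]],
      ultra_rare = if ("ultra_rare" %in% names(svs)) .data$ultra_rare else NA,
      constrained = if ("constrained" %in% names(svs)) .data$constrained else NA,
      acmg_class = if ("acmg_class" %in% names(svs)) .data$acmg_class else NA_integer_
    )
  }

  counts <- tibble::tibble(
    case_alleles = as.integer(tab$case_carriers),
    case_allele_number = as.integer(n_case),
    panel_alleles = as.integer(tab$ref_carriers),
    panel_allele_number = as.integer(n_ref)
  )
  tested <- burden_test(counts, alpha = alpha)
  out <- dplyr::bind_cols(
    tab,
    dplyr::select(tested, "chi2", "p_value", "odds_ratio", "ci_low",
                  "ci_high", "enriched")
  ) |>
    dplyr::mutate(
      case_freq = round(.data$case_carriers / n_case, 3),
      ref_freq = round(.data$ref_carriers / n_ref, 3),
      .after = "ref_carriers"
    ) |>
    dplyr::arrange(.data$p_value,
                   dplyr::desc(dplyr::coalesce(.data$odds_ratio, -Inf)))
  structure(out, class = c("sv_burden", class(tibble::as_tibble(out))),
            case = case, reference = reference, alpha = alpha,
            cohort_sizes = cohort_sizes)
}

#' Apply the full SV prioritization chain
#'
#' Size window (with the known-SV rescue path for oversized calls),
#' blacklist-artifact removal, known-SV concordance, ACMG-style
#' classification with classes 3-5 retained, constrained-gene overlap and
#' ultra-rare flagging, in the documented order.
#'
#' @param svs Raw SV call tibble.
#' @param blacklist,known Region and known-SV tibbles.
#' @param gene_intervals,constraint Gene intervals and constraint table.
#' @param reference Reference cohort name for ultra-rare flagging.
#' @param cohort_sizes Named cohort sizes.
#' @param rules ACMG rubric.
#' @param min_bp,max_bp,blacklist_threshold,known_threshold,max_ref_freq
#'   Stage thresholds (documented defaults).
#' @return The prioritized SV tibble with all stage annotations.
#' @export
sv_prioritize <- function(svs, blacklist, known, gene_intervals, constraint,
                          reference, cohort_sizes,
                          rules = acmg_default_rules(),
                          min_bp = 1000, max_bp = 1000000,
                          blacklist_threshold = 0.66, known_threshold = 0.99,
                          max_ref_freq = 0.001) {
  sized <- sv_filter_size(svs, min_bp, max_bp)
  rescued <- sv_filter_known(sized$oversized, known, known_threshold)
  pool <- dplyr::bind_rows(sized$kept, rescued)
  pool <- sv_filter_artifacts(pool, blacklist, blacklist_threshold)
  pool <- sv_filter_known(pool, known, known_threshold)
  pool <- sv_constrained_overlap(pool, gene_intervals, constraint)
  if (!"constrained_gene_overlap" %in% names(pool)) {
    pool$constrained_gene_overlap <- pool$constrained
  }
  pool <- sv_classify_acmg(pool, rules)
  pool <- retain_reportable(pool)
  sv_flag_ultra_rare(pool, reference, cohort_sizes, max_ref_freq)
}
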