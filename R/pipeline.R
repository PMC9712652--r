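# End-to-end orchestration: simulate (optional) -> classify -> gene burden
# (discovery, severe subset, replication) -> SV prioritization and burden ->
# clinical comparisons, with TSV outputs and a reproducibility manifest.

default_thresholds <- function() {
  list(
    maf = 0.01, cadd = 20, pli = 0.9, loeuf = 0.5, loeuf_bin = 2,
    blacklist = 0.66, known_sv = 0.99, sv_size = c(1000, 1000000),
    ultra_rare = 0.001, thi = 58, tfi = 48, alpha = 0.05
  )
}

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: all stage thresholds (with
#' their documented defaults), the counting mode, the seed, and the
#' simulation config supplying the inputs. Unknown keys and out-of-domain
#' thresholds are rejected up front, before any stage runs.
#'
#' @param thresholds Named list overriding entries of the default threshold
#'   set (maf 0.01, cadd 20, pli 0.9, loeuf 0.5, loeuf_bin 2, blacklist 0.66,
#'   known_sv 0.99, sv_size 1 kb - 1 Mb, ultra_rare 0.001, thi 58, tfi 48,
#'   alpha 0.05).
#' @param counting `"alleles"` (SNV collapsing) or `"carriers"`.
#' @param sim A [simulation_config()] providing the synthetic inputs.
#' @param seed Seed recorded in the manifest; overrides the simulation seed.
#' @param output_dir Where [run_pipeline()] writes its files.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = list(), counting = "alleles",
                            sim = simulation_config(), seed = sim$seed,
                            output_dir = tempfile("tinburden_run_")) {
  defaults <- default_thresholds()
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0) {
    abort_config(sprintf("Unknown threshold key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  thresholds <- utils::modifyList(defaults, thresholds)
  checks <- list(
    maf = c(0, 1), cadd = c(0, Inf), pli = c(0, 1), loeuf = c(0, Inf),
    loeuf_bin = c(0, 9), blacklist = c(0, 1), known_sv = c(0, 1),
    ultra_rare = c(0, 1), thi = c(0, 100), tfi = c(0, 100), alpha = c(0, 1)
  )
  for (key in names(checks)) {
    v <- thresholds[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < checks[[key]][1] || v > checks[[key]][2]) {
      abort_config(sprintf("Threshold `%s` outside its domain [%g, %g].",
                           key, checks[[key]][1], checks[[key]][2]))
    }
  }
  if (length(thresholds$sv_size) != 2 ||
      thresholds$sv_size[1] >= thresholds$sv_size[2]) {
    abort_config("Threshold `sv_size` must be an increasing pair of lengths.")
  }
  if (!counting %in% c("alleles", "carriers")) {
    abort_config("`counting` must be \"alleles\" or \"carriers\".")
  }
  if (!inherits(sim, "sim_config")) {
    abort_config("`sim` must be a simulation_config().")
  }
  if (!identical(seed, sim$seed)) {
    sim$seed <- as.integer(seed)
  }
  structure(
    list(thresholds = thresholds, counting = counting, sim = sim,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The file may define `thresholds`, `counting`, `seed`, `output_dir` and a
#' `sim` block of [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  unknown <- setdiff(names(spec), c("thresholds", "counting", "seed",
                                    "output_dir", "sim"))
  if (length(unknown) > 0) {
    abort_config(sprintf("Unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  sim_args <- spec$sim %||% list()
  if (!is.null(spec$seed)) sim_args$seed <- spec$seed
  sim <- do.call(simulation_config, sim_args)
  args <- list(thresholds = spec$thresholds %||% list(),
               counting = spec$counting %||% "alleles", sim = sim)
  if (!is.null(spec$seed)) args$seed <- spec$seed
  if (!is.null(spec$output_dir)) args$output_dir <- spec$output_dir
  do.call(pipeline_config, args)
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  readr::write_tsv(tibble::as_tibble(x), path)
  path
}

#' Run the full pipeline on a simulated study
#'
#' Generates the synthetic study (reference panel, discovery and replication
#' cohorts, constraint table, SV call set, clinical table), writes the inputs
#' to disk in their external formats, reads them back through the package's
#' own readers, and runs classification, the gene burden for discovery /
#' severe subset / replication with cross-cohort replication, the SV
#' prioritization chain and carrier burden, and the clinical comparisons.
#' All stage outputs are written as TSV beside a manifest recording the seed
#' and a config hash; identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list of stage tibbles and file paths,
#'   invisibly printable via [render_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thr <- config$thresholds
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(config$output_dir, "inputs")
  out_dir <- file.path(config$output_dir, "outputs")
  dir.create(in_dir, showWarnings = FALSE)
  dir.create(out_dir, showWarnings = FALSE)
  sim <- config$sim
  log_counts <- list()

  # --- simulate and round-trip the inputs through their external formats
  panel <- simulate_reference_panel(sim)
  discovery <- simulate_case_cohort(sim, panel, "discovery")
  replication <- simulate_case_cohort(sim, panel, "replication")
  svset <- simulate_sv_callset(sim)
  clinical_raw <- simulate_clinical_table(sim)

  vcf_path <- file.path(in_dir, "discovery.vcf")
  write_variant_vcf(discovery$variants, vcf_path)
  variants <- read_variant_vcf(vcf_path)
  constraint_path <- write_stage(svset$constraint, in_dir, "constraint")
  constraint <- read_constraint_table(constraint_path)
  sv_path <- write_stage(svset$svs, in_dir, "sv_calls")
  svs <- read_sv_calls(sv_path, cohort_sizes = svset$cohort_sizes)
  bl_path <- write_regions_bed(svset$regions$blacklist,
                               file.path(in_dir, "blacklist.bed"))
  blacklist <- read_regions_bed(bl_path, "blacklist")
  clin_path <- file.path(in_dir, "clinical.csv")
  write_clinical(clinical_raw, clin_path)
  clinical <- read_clinical(clin_path)

  # --- classify + gene burden
  variants <- annotate_variants(variants, constraint = constraint,
                                maf_threshold = thr$maf,
                                cadd_threshold = thr$cadd)
  gba_discovery <- run_gene_burden(variants, sim$n_cases,
                                   constraint = constraint,
                                   alpha = thr$alpha,
                                   maf_threshold = thr$maf)
  severe_ids <- discovery$samples$sample_id[discovery$samples$severe]
  gba_severe <- run_gene_burden(subset_samples(variants, severe_ids),
                                sim$n_severe, constraint = constraint,
                                alpha = thr$alpha, maf_threshold = thr$maf)
  gba_replication <- run_gene_burden(replication$variants, sim$n_replication,
                                     constraint = constraint,
                                     alpha = thr$alpha,
                                     maf_threshold = thr$maf)
  replicated <- replicate_burden(gba_discovery, gba_replication)
  enriched_genes <- unique(tibble::as_tibble(gba_discovery) |>
                             dplyr::filter(.data$enriched) |>
                             dplyr::pull("gene"))
  multihit <- find_multihit_carriers(variants, enriched_genes)

  # --- SV prioritization + carrier burden
  sv_kept <- sv_prioritize(
    svs, blacklist, svset$known, svset$gene_intervals, constraint,
    reference = "reference", cohort_sizes = svset$cohort_sizes,
    min_bp = thr$sv_size[1], max_bp = thr$sv_size[2],
    blacklist_threshold = thr$blacklist, known_threshold = thr$known_sv,
    max_ref_freq = thr$ultra_rare
  )
  log_counts$svs_in <- nrow(svs)
  log_counts$svs_kept <- nrow(sv_kept)
  svb <- sv_burden(sv_kept, "cases", "reference", svset$cohort_sizes,
                   alpha = thr$alpha)
  svb_ultra <- sv_burden(sv_kept[sv_kept$ultra_rare & sv_kept$constrained, ,
                                 drop = FALSE],
                         "cases", "reference", svset$cohort_sizes,
                         alpha = thr$alpha)

  # --- clinical comparisons
  chronic <- select_chronic(clinical, thr$tfi)
  severe_clin <- select_severe(chronic, thr$thi)
  clinical_cmp <- compare_categorical(chronic, severe_clin)
  log_counts$chronic <- nrow(chronic)
  log_counts$severe <- nrow(severe_clin)

  outputs <- list(
    gba_discovery = gba_discovery, gba_severe = gba_severe,
    gba_replication = gba_replication, replicated = replicated,
    multihit = multihit, sv_prioritized = sv_kept, sv_burden = svb,
    sv_burden_ultra_rare = svb_ultra, clinical_comparison = clinical_cmp
  )
  paths <- purrr::imap(outputs, function(x, nm) {
    write_stage(drop_list_columns(x), out_dir, nm)
  })

  manifest <- list(
    package = "tinburden",
    version = as.character(utils::packageVersion("tinburden")),
    seed = config$seed,
    config_hash = rlang::hash(config[c("thresholds", "counting", "sim")]),
    thresholds = config$thresholds,
    counting = config$counting,
    stage_counts = log_counts
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  structure(
    c(outputs,
      list(truth = list(genes = discovery$truth, svs = svset$truth),
           paths = c(paths, manifest = manifest_path),
           config = config)),
    class = "pipeline_result"
  )
}

drop_list_columns <- function(x) {
  x <- tibble::as_tibble(x)
  x[, !vapply(x, is.list, logical(1)), drop = FALSE]
}

#' Render pipeline outputs as markdown tables
#'
#' Formats the clinical comparison with "count (whole %)" cells, the SV
#' burden with "count (frequency to 3 decimals)" cells, and renders p-values
#' below 0.001 as "<0.001".
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param top_genes Number of top burden rows to show.
#' @return A character scalar of markdown, invisibly also printed.
#' @export
render_report <- function(result, top_genes = 10) {
  stopifnot(inherits(result, "pipeline_result"))
  md <- c("# Burden analysis report", "")

  clin <- result$clinical_comparison
  md <- c(md, "## Clinical features (chronic vs severe)", "",
          "| Feature | Chronic | Severe | p value |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %s | %s |",
                  clin$feature,
                  fmt_pct_cell(clin$count_a, clin$total_a),
                  fmt_pct_cell(clin$count_b, clin$total_b),
                  fmt_p(clin$p_value)),
          "")

  gba <- head(tibble::as_tibble(result$gba_discovery), top_genes)
  md <- c(md, "## Top gene burden results (discovery)", "",
          "| Gene | Class | OR (95% CI) | p value |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %.2f (%.2f-%.2f) | %s |",
                  gba$gene, gba$variant_class, gba$odds_ratio, gba$ci_low,
                  gba$ci_high, fmt_p(gba$p_value)),
          "")

  svb <- tibble::as_tibble(result$sv_burden)
  sizes <- attr(result$sv_burden, "cohort_sizes")
  md <- c(md, "## Structural-variant burden (cases vs reference)", "",
          "| SV | Type | Cases | Reference | p value |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s | %s | %s | %s |",
                  svb$sv_id, svb$sv_type,
                  fmt_freq_cell(svb$case_carriers, sizes[["cases"]]),
                  fmt_freq_cell(svb$ref_carriers, sizes[["reference"]]),
                  fmt_p(svb$p_value)),
          "")
  out <- paste(md, collapse = "\n")
  invisible(out)
}
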