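# Collapsing gene-burden test against external reference panels.
#
# Per gene and variant class, rare qualifying alleles are summed over sites
# ("collapsed") in cases and in the panel, giving a 2x2 table of alt vs
# non-alt chromosomes. The table is tested by a Pearson chi-squared statistic
# (1 df, no continuity correction) on the raw cells; the odds ratio and its
# Wald 95% CI, exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)), use a
# Haldane-Anscombe +0.5 on all cells whenever any cell is zero, keeping the
# p-value and the effect estimate decoupled.

#' Collapse rare variants per gene and class against one panel
#'
#' @param variants Rarity-filtered variant tibble with `variant_class` (or a
#'   `consequence` column to classify on the fly), `ac_case`, `an_case`, and
#'   `ac_<panel>`/`an_<panel>` columns.
#' @param n_cases Number of case samples (allele number is `2 * n_cases`).
#' @param panel Name of the reference panel to collapse against.
#' @param classes Variant classes to keep (default LOF and MISSENSE).
#' @param by_class Collapse per class (default) or pool classes per gene.
#' @param damaging_only Restrict MISSENSE to CADD-damaging sites.
#' @return Tibble of collapsed counts: `gene`, `variant_class`,
#'   `case_alleles`, `case_allele_number`, `panel_alleles`,
#'   `panel_allele_number`, `n_variants`. Sites missing from the panel
#'   contribute 0 alleles against the declared panel allele number. Genes with
#'   no qualifying site emit no row.
#' @export
collapse_gene_counts <- function(variants, n_cases, panel,
                                 classes = c("LOF", "MISSENSE"),
                                 by_class = TRUE,
                                 damaging_only = FALSE) {
  if (!is_count(n_cases)) abort_validation("`n_cases` must be a positive integer.")
  ac_col <- paste0("ac_", panel)
  an_col <- paste0("an_", panel)
  if (!all(c(ac_col, an_col) %in% names(variants))) {
    abort_config(sprintf("Panel `%s` columns not found in `variants`.", panel))
  }
  if (!"variant_class" %in% names(variants)) {
    variants$variant_class <- classify_consequence(variants$consequence)
  }
  keep <- variants$variant_class %in% classes & !is.na(variants$gene) &
    nzchar(variants$gene)
  if (any(is.na(variants$gene) | !nzchar(variants$gene))) {
    notify("Rows with missing gene symbol skipped during collapsing.")
  }
  if (damaging_only) {
    dmg <- is_damaging(variants$cadd)
    keep <- keep & (variants$variant_class != "MISSENSE" | dmg)
  }
  v <- variants[keep, , drop = FALSE]
  if (nrow(v) == 0) {
    return(tibble::tibble(
      gene = character(), variant_class = character(),
      case_alleles = integer(), case_allele_number = integer(),
      panel_alleles = integer(), panel_allele_number = integer(),
      n_variants = integer()
    ))
  }
  panel_an <- max(v[[an_col]], na.rm = TRUE)
  grouping <- if (by_class) c("gene", "variant_class") else "gene"
  out <- v |>
    dplyr::mutate(variant_class = as.character(.data$variant_class)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      case_alleles = as.integer(sum(.data$ac_case)),
      panel_alleles = as.integer(sum(dplyr::coalesce(.data[[ac_col]], 0L))),
      n_variants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      case_allele_number = 2L * as.integer(n_cases),
      panel_allele_number = as.integer(panel_an)
    )
  if (!by_class) out$variant_class <- "ALL"
  dplyr::select(out, "gene", "variant_class", "case_alleles",
                "case_allele_number", "panel_alleles", "panel_allele_number",
                "n_variants")
}

# Pearson chi-squared (no continuity correction) for one 2x2 table of
# non-negative counts; degenerate margins give statistic 0, p = 1.
chi2_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(c(statistic = 0, p_value = 1))
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  c(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

fisher_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(c(statistic = NA_real_, p_value = 1))
  }
  ft <- fisher.test(m)
  c(statistic = NA_real_, p_value = ft$p.value)
}

#' Test collapsed gene counts for case enrichment
#'
#' Builds, per row, the 2x2 table (case alt alleles, case non-alt alleles;
#' panel alt alleles, panel non-alt alleles) and computes the Pearson
#' chi-squared statistic without continuity correction with its 1-df p-value
#' (Fisher's exact test optionally instead), the odds ratio (a d)/(b c), and
#' the Wald 95% confidence interval on ln OR. When any cell is zero the OR
#' and CI use Haldane-Anscombe corrected cells (+0.5 everywhere); the
#' chi-squared always uses the raw cells. Tables with an empty margin are
#' degenerate: p = 1, OR reported missing.
#'
#' The same construction serves carrier counting (samples vs samples) by
#' passing carrier counts and cohort sizes in place of allele counts and
#' allele numbers.
#'
#' @param counts Output of [collapse_gene_counts()] (or any tibble with the
#'   same count columns).
#' @param alpha Enrichment significance level (default 0.05).
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return `counts` with appended `a`, `b`, `c`, `d`, `chi2`, `p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `enriched` (p < alpha and OR > 1).
#' @export
#' @examples
#' counts <- tibble::tibble(
#'   gene = "TMEM132D", variant_class = "SV", case_alleles = 21L,
#'   case_allele_number = 97L, panel_alleles = 17L, panel_allele_number = 1000L
#' )
#' burden_test(counts)[, c("odds_ratio", "p_value")]
burden_test <- function(counts, alpha = 0.05, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (nrow(counts) == 0) {
    return(dplyr::mutate(counts, a = integer(), b = integer(), c = integer(),
                         d = integer(), chi2 = numeric(), p_value = numeric(),
                         odds_ratio = numeric(), ci_low = numeric(),
                         ci_high = numeric(), enriched = logical()))
  }
  if (any(counts$case_allele_number <= 0 | counts$panel_allele_number <= 0)) {
    abort_validation("Allele numbers (cohort sizes) must be positive.")
  }
  if (any(counts$case_alleles < 0 | counts$panel_alleles < 0 |
          counts$case_alleles > counts$case_allele_number |
          counts$panel_alleles > counts$panel_allele_number)) {
    abort_validation("Counts must be non-negative and bounded by their totals.")
  }
  a <- counts$case_alleles
  b <- counts$case_allele_number - a
  c_ <- counts$panel_alleles
  d <- counts$panel_allele_number - c_

  test_fun <- if (method == "chisq") chi2_2x2 else fisher_2x2
  stats <- purrr::pmap(list(a, b, c_, d), test_fun)
  chi2 <- vapply(stats, `[[`, numeric(1), "statistic")
  p <- vapply(stats, `[[`, numeric(1), "p_value")

  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  ha <- 0.5 * zero
  aa <- a + ha; bb <- b + ha; cc <- c_ + ha; dd <- d + ha
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ci_low <- exp(log(or) - 1.96 * se)
  ci_high <- exp(log(or) + 1.96 * se)

  degenerate <- (a + c_) == 0 | (b + d) == 0
  or[degenerate] <- NA_real_
  ci_low[degenerate] <- NA_real_
  ci_high[degenerate] <- NA_real_

  dplyr::mutate(counts,
    a = a, b = b, c = c_, d = d,
    chi2 = chi2, p_value = p,
    odds_ratio = or, ci_low = ci_low, ci_high = ci_high,
    enriched = .data$p_value < alpha & !is.na(or) & or > 1
  )
}

#' Run the full gene burden analysis for one cohort
#'
#' Classifies, rarity-filters (strictly below `maf_threshold` in every
#' supplied panel), collapses per gene x class against each panel, and tests
#' every collapsed table. Results are sorted by p ascending, then OR
#' descending, then gene symbol.
#'
#' @param variants Cohort variant tibble (from [read_variant_vcf()] or
#'   [simulate_case_cohort()]).
#' @param n_cases Cohort sample count.
#' @param panels Panel names to test against; default all panels present.
#' @param constraint Optional constraint table; attaches
#'   `intolerant_pli`/`intolerant_loeuf` flags.
#' @param classes Variant classes collapsed (default LOF and MISSENSE).
#' @param alpha Enrichment significance level.
#' @param maf_threshold Rarity threshold (default 0.01).
#' @param damaging_only Restrict MISSENSE to CADD-damaging sites (default
#'   FALSE: all rare missense variants enter the headline analysis).
#' @param method `"chisq"` or `"fisher"`.
#' @param adjust Optional multiple-testing adjustment appended as
#'   `p_adjusted` (`"none"`, `"bonferroni"`, `"BH"`); unadjusted p-values are
#'   always reported.
#' @return A `gba` tibble: one row per gene x class x panel with counts,
#'   chi2, p, OR, CI, enrichment and constraint flags.
#' @export
run_gene_burden <- function(variants, n_cases, panels = NULL,
                            constraint = NULL,
                            classes = c("LOF", "MISSENSE"),
                            alpha = 0.05, maf_threshold = 0.01,
                            damaging_only = FALSE,
                            method = c("chisq", "fisher"),
                            adjust = c("none", "bonferroni", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  panels <- panels %||% panel_names(variants)
  if (length(panels) == 0) abort_config("No reference panels available.")

  empty <- tibble::tibble(
    gene = character(), variant_class = character(), panel = character(),
    case_alleles = integer(), case_allele_number = integer(),
    panel_alleles = integer(), panel_allele_number = integer(),
    n_variants = integer(), a = integer(), b = integer(), c = integer(),
    d = integer(), chi2 = numeric(), p_value = numeric(),
    odds_ratio = numeric(), ci_low = numeric(), ci_high = numeric(),
    enriched = logical()
  )
  if (nrow(variants) == 0) {
    return(new_gba(empty, alpha = alpha, n_cases = n_cases, panels = panels))
  }

  if (!"variant_class" %in% names(variants)) {
    variants$variant_class <- classify_consequence(variants$consequence)
  }
  rare <- is_rare(variants, panels, maf_threshold)
  v <- variants[rare, , drop = FALSE]

  res <- purrr::map_dfr(panels, function(p) {
    collapse_gene_counts(v, n_cases, p, classes = classes,
                         damaging_only = damaging_only) |>
      burden_test(alpha = alpha, method = method) |>
      dplyr::mutate(panel = p, .after = "variant_class")
  })
  if (nrow(res) == 0) {
    return(new_gba(empty, alpha = alpha, n_cases = n_cases, panels = panels))
  }
  if (!is.null(constraint)) {
    res <- dplyr::left_join(res, constraint_flags(unique(res$gene), constraint),
                            by = "gene")
  }
  if (adjust != "none") {
    res$p_adjusted <- p.adjust(res$p_value, method = adjust)
  }
  res <- dplyr::arrange(res, .data$p_value,
                        dplyr::desc(dplyr::coalesce(.data$odds_ratio, -Inf)),
                        .data$gene)
  new_gba(res, alpha = alpha, n_cases = n_cases, panels = panels)
}

new_gba <- function(x, alpha, n_cases, panels) {
  structure(x, class = c("gba", class(tibble::as_tibble(x))),
            alpha = alpha, n_cases = n_cases, panels = panels)
}

#' Cross-cohort replication of enriched genes
#'
#' A gene (within a variant class) is replicated iff it is enriched (OR > 1,
#' p < alpha) against at least one panel in the discovery cohort AND against
#' at least one panel in the replication cohort. The supporting comparisons
#' are recorded.
#'
#' @param discovery,replication `gba` results for the two cohorts.
#' @return Tibble: `gene`, `variant_class`, `discovery_panels`,
#'   `replication_panels`, `replicated` (always TRUE in emitted rows).
#' @export
replicate_burden <- function(discovery, replication) {
  hits <- function(res) {
    res |>
      tibble::as_tibble() |>
      dplyr::filter(.data$enriched) |>
      dplyr::group_by(.data$gene, .data$variant_class) |>
      dplyr::summarise(panels = paste(sort(unique(.data$panel)),
                                      collapse = ","),
                       .groups = "drop")
  }
  d <- hits(discovery)
  r <- hits(replication)
  dplyr::inner_join(d, r, by = c("gene", "variant_class"),
                    suffix = c("_discovery", "_replication")) |>
    dplyr::rename(discovery_panels = "panels_discovery",
                  replication_panels = "panels_replication") |>
    dplyr::mutate(replicated = TRUE) |>
    dplyr::arrange(.data$gene, .data$variant_class)
}

#' Subjects carrying two or more qualifying variants in the same gene
#'
#' Counts, per subject and listed gene, distinct variant sites (not alleles:
#' one homozygous site counts once) at which the subject carries at least one
#' alternate allele, and reports subjects with two or more such sites.
#'
#' @param variants Variant tibble with a `gt` genotype list-column.
#' @param genes Genes of interest (e.g. the enriched set).
#' @param classes Qualifying variant classes.
#' @return Tibble `subject_id`, `gene`, `n_sites` (>= 2).
#' @export
find_multihit_carriers <- function(variants, genes,
                                   classes = c("LOF", "MISSENSE")) {
  if (!"gt" %in% names(variants)) {
    abort(paste("Per-sample genotypes are required to find multi-hit",
                "carriers, but `variants` has no `gt` column."),
          class = "tinburden_capability_error")
  }
  empty <- tibble::tibble(subject_id = character(), gene = character(),
                          n_sites = integer())
  if (length(genes) == 0) return(empty)
  if (!"variant_class" %in% names(variants)) {
    variants$variant_class <- classify_consequence(variants$consequence)
  }
  v <- variants[variants$gene %in% genes &
                  variants$variant_class %in% classes, , drop = FALSE]
  if (nrow(v) == 0) return(empty)
  per_gene <- split(v$gt, v$gene)
  purrr::imap_dfr(per_gene, function(gts, g) {
    carrier <- vapply(gts, function(d) !is.na(d) & d >= 1,
                      logical(length(gts[[1]])))
    n_sites <- if (is.matrix(carrier)) rowSums(carrier) else as.integer(carrier)
    hit <- which(n_sites >= 2)
    tibble::tibble(subject_id = names(gts[[1]])[hit], gene = g,
                   n_sites = as.integer(n_sites[hit]))
  }) |>
    dplyr::arrange(.data$gene, .data$subject_id)
}
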