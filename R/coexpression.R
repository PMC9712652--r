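# Probe-probe correlation and cross-gene regional co-expression from a
# probes x regions expression matrix (the correlation step of a brain-atlas
# microarray analysis; atlas retrieval itself is out of scope).

region_columns <- function(mat) {
  setdiff(names(mat), c("probe_id", "gene"))
}

#' Pairwise probe correlations within a gene
#'
#' Pearson correlation and two-sided p-value for every pair of probes
#' annotated to the gene, computed across regions. Probes with zero variance
#' yield a missing correlation.
#'
#' @param mat Expression tibble (`probe_id`, `gene`, one numeric column per
#'   region; at least two regions).
#' @param gene Gene symbol with at least two probes.
#' @return Tibble `probe_a`, `probe_b`, `estimate`, `p_value`, `n_regions`.
#' @export
probe_correlations <- function(mat, gene) {
  regions <- region_columns(mat)
  if (length(regions) < 2) {
    abort_validation("At least two regions are required for correlations.")
  }
  probes <- mat[mat$gene == gene, , drop = FALSE]
  if (nrow(probes) < 2) {
    abort_validation(sprintf("Gene %s has fewer than two probes.", gene))
  }
  expr <- as.matrix(probes[, regions])
  pairs <- utils::combn(nrow(probes), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- expr[i1, ]; y <- expr[i2, ]
    if (sd(x) == 0 || sd(y) == 0) {
      est <- NA_real_; p <- NA_real_
    } else {
      ct <- cor.test(x, y, method = "pearson")
      est <- unname(ct$estimate); p <- ct$p.value
    }
    tibble::tibble(probe_a = probes$probe_id[i1], probe_b = probes$probe_id[i2],
                   estimate = est, p_value = p, n_regions = length(x))
  })
}

# Probes representing a gene: for multi-probe genes, the probes appearing in
# at least one significantly correlated pair; single-probe genes are
# represented by their probe.
selected_probes <- function(mat, gene, p_threshold) {
  probes <- mat$probe_id[mat$gene == gene]
  if (length(probes) == 0) {
    abort_validation(sprintf("Gene %s has no probes in the matrix.", gene))
  }
  if (length(probes) == 1) return(probes)
  corr <- probe_correlations(mat, gene)
  sig <- corr[!is.na(corr$p_value) & corr$p_value < p_threshold, ]
  sel <- unique(c(sig$probe_a, sig$probe_b))
  if (length(sel) == 0) {
    abort_validation(sprintf(
      "Gene %s has no probe pair with correlation p < %g.", gene, p_threshold))
  }
  sel
}

#' Regions where a set of genes is jointly expressed
#'
#' For each gene, probes are first reduced to those with significantly
#' correlated expression (two-sided p below `p_threshold`; a single-probe
#' gene keeps its probe). A region is reported iff every listed gene has at
#' least one selected probe whose expression exceeds the threshold there.
#' The default threshold is each probe's own row median, so "expressed"
#' means above that probe's typical level.
#'
#' @param mat Expression tibble.
#' @param genes Gene symbols.
#' @param expression_threshold A single numeric applied to all probes, or
#'   `NULL` (default) for the per-probe row median.
#' @param p_threshold Probe-pair correlation significance level (default
#'   0.05).
#' @return Tibble `region`, `n_genes_expressed` (= number of listed genes),
#'   one row per co-expressed region, in column order of the matrix.
#' @export
coexpressed_regions <- function(mat, genes, expression_threshold = NULL,
                                p_threshold = 0.05) {
  regions <- region_columns(mat)
  ok <- rep(TRUE, length(regions))
  for (g in genes) {
    sel <- selected_probes(mat, g, p_threshold)
    expr <- as.matrix(mat[mat$probe_id %in% sel, regions, drop = FALSE])
    thr <- if (is.null(expression_threshold)) {
      apply(expr, 1, median)
    } else {
      rep(expression_threshold, nrow(expr))
    }
    ok <- ok & apply(expr > thr, 2, any)
  }
  tibble::tibble(region = regions[ok],
                 n_genes_expressed = length(genes))
}
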