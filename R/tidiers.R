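# broom-style accessors for the two fitted result types.

#' Tidy a gene burden result
#'
#' @param x A `gba` object from [run_gene_burden()].
#' @param ... Unused.
#' @return A plain tibble of per-gene results.
#' @exportS3Method generics::tidy
tidy.gba <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "gba")
  out
}

#' One-row summary of a gene burden result
#'
#' @param x A `gba` object.
#' @param ... Unused.
#' @return Tibble with the number of genes, tests, enriched hits, the
#'   minimum p-value and the significance level used.
#' @exportS3Method generics::glance
glance.gba <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(
    n_genes = dplyr::n_distinct(tb$gene),
    n_tests = nrow(tb),
    n_enriched = sum(tb$enriched, na.rm = TRUE),
    min_p = if (nrow(tb)) min(tb$p_value) else NA_real_,
    alpha = attr(x, "alpha")
  )
}

#' @rdname tidy.gba
#' @exportS3Method generics::tidy
tidy.sv_burden <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "sv_burden")
  out
}

#' @rdname glance.gba
#' @exportS3Method generics::glance
glance.sv_burden <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tibble::tibble(
    n_svs = nrow(tb),
    n_enriched = sum(tb$enriched, na.rm = TRUE),
    min_p = if (nrow(tb)) min(tb$p_value) else NA_real_,
    alpha = attr(x, "alpha")
  )
}
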