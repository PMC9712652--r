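# ggplot2 displays for the two result types.

#' Forest plot of gene burden results
#'
#' Odds ratios with Wald 95% intervals for the top genes by p-value, faceted
#' by variant class, on a log OR axis.
#'
#' @param object A `gba` object from [run_gene_burden()].
#' @param top Number of rows to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gba <- function(object, top = 20, ...) {
  tb <- tidy(object) |>
    dplyr::filter(!is.na(.data$odds_ratio)) |>
    dplyr::slice_min(.data$p_value, n = top, with_ties = FALSE)
  ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$odds_ratio,
    y = stats::reorder(paste(.data$gene, .data$panel), -.data$p_value),
    colour = .data$enriched
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variant_class), scales = "free_y") +
    ggplot2::labs(x = "Odds ratio (cases vs panel, log scale)", y = NULL,
                  colour = "Enriched") +
    ggplot2::theme_minimal()
}

#' Carrier-frequency plot of SV burden results
#'
#' Case vs reference carrier frequency per structural variant, sized by
#' -log10 p; points above the diagonal are case-enriched.
#'
#' @param object An `sv_burden` object from [sv_burden()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sv_burden <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$ref_freq, y = .data$case_freq,
                                   colour = .data$sv_type,
                                   size = -log10(.data$p_value))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Reference carrier frequency",
                  y = "Case carrier frequency",
                  colour = "Type", size = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of clinical feature proportions
#'
#' @param comparison Output of [compare_categorical()].
#' @param labels Length-2 names for the two groups.
#' @return A ggplot object.
#' @export
plot_clinical_comparison <- function(comparison, labels = c("group A", "group B")) {
  long <- tidyr::pivot_longer(
    comparison,
    cols = c("pct_a", "pct_b"),
    names_to = "group", values_to = "pct"
  ) |>
    dplyr::mutate(group = ifelse(.data$group == "pct_a", labels[1], labels[2]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Prevalence (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
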