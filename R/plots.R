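#' Volcano-style view of level-1 differential calls
#'
#' Plots the mean log2 difference of every consensus region against
#' -log10 of the Fisher P value, with the fold-change and significance
#' cutoffs drawn as reference lines and passed calls highlighted.
#'
#' @param object A `level1_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot level1_calls
#' @export
autoplot.level1_calls <- function(object, ...) {
  df <- tibble::as_tibble(object)
  cutoff <- attr(object, "effect_cutoff") %||% log2(1.05)
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_log2,
                                   y = -log10(.data$p_value),
                                   colour = .data$passed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-cutoff, cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean log2(MIRA/input) difference (A - B)",
                  y = "-log10 Fisher P",
                  title = attr(object, "test_id") %||% "level-1 calls") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression contrast
#'
#' @param object A `de_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_results
#' @export
autoplot.de_results <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold_change,
                                   y = -log10(.data$p_value),
                                   colour = .data$passed)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P",
                  title = sprintf("differential expression (%s profile)",
                                  attr(object, "profile"))) +
    ggplot2::theme_minimal()
}

#' Region-average methylation by imprinting class
#'
#' Displays per-replicate region means ordered by class, the view used to
#' confirm that paternally methylated DMRs sit above zero and maternally
#' methylated DMRs below it in male germline samples.
#'
#' @param region_means Output of [region_mean()].
#' @return A ggplot object.
#' @export
plot_region_means <- function(region_means) {
  ggplot2::ggplot(region_means,
                  ggplot2::aes(x = stats::reorder(.data$name, .data$mean_log2),
                               y = .data$mean_log2,
                               colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean log2(MIRA/input)") +
    ggplot2::theme_minimal()
}

#' Mixing-series calibration plot
#'
#' Corrected observations against true input percentages with the
#' identity line and the fitted regression.
#'
#' @param true_pct,observed_pct Mixing-series percentages as in
#'   [linearity_check()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(true_pct, observed_pct) {
  df <- tibble::tibble(true_pct = true_pct, observed_pct = observed_pct)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_pct,
                                   y = .data$observed_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true maternal %", y = "observed maternal %") +
    ggplot2::theme_minimal()
}
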