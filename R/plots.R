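#' Heatmap of normalized odds ratios
#'
#' The standard presentation of a scored cohort: samples as rows, lineages
#' as columns, tile fill = normalized odds ratio from 0 to 1.
#'
#' @param object A `ct_result` from [score_cohort()] (normalized).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ct_result
#' @export
autoplot.ct_result <- function(object, ...) {
  if (!"norm_odds_ratio" %in% names(object)) {
    object <- normalize_odds_ratios(object)
  }
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lineage, y = .data$sample,
                               fill = .data$norm_odds_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "normalized\nodds ratio") +
    ggplot2::labs(x = "cell type", y = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.ct_result
#' @export
plot_enrichment_heatmap <- function(object, ...) autoplot.ct_result(object, ...)

#' Spike-in detection curve plot
#'
#' -log10 p of the paired spiked-vs-unspiked test as a function of the
#' spike fraction, with the significance threshold as a dashed line.
#'
#' @param object A `ct_detection` from [detection_limit_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ct_detection
#' @export
autoplot.ct_detection <- function(object, ...) {
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fraction, y = .data$neglog10_p,
                               colour = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "spike-in fraction", y = expression(-log[10]~italic(p)),
                  colour = "cell type") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ct_detection
#' @export
plot_detection_curve <- function(object, ...) autoplot.ct_detection(object, ...)
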