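# ggplot2 graphics for the main result types.

#' Plot completeness/contiguity against the coverage threshold
#'
#' @param curves a [metric_curve()] tibble, or the `curves` element of an
#'   [evaluate_assemblies()] report (with a `label` column for facetting).
#' @return a ggplot.
#' @export
plot_metric_curve <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("completeness", "contiguity"),
                              names_to = "metric", values_to = "percent")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                          y = .data$percent,
                                          colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "coverage threshold", y = "% of expressed references",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("label" %in% names(curves)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$label))
  }
  p
}

#' Histogram of Ortholog Hit Ratios
#'
#' @param ohr an [ortholog_hit_ratio()] tibble.
#' @param binwidth histogram bin width (default 0.05).
#' @return a ggplot. A pile-up near 1.0 means transcripts assembled to
#'   full reference length.
#' @export
plot_ohr_histogram <- function(ohr, binwidth = 0.05) {
  ggplot2::ggplot(ohr, ggplot2::aes(x = .data$ohr)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Ortholog Hit Ratio", y = "contigs") +
    ggplot2::theme_minimal()
}

#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$log_dil,
                                            y = .data$cp)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(dilution)", y = "Cp",
      title = if (!is.na(object$gene_id)) object$gene_id else NULL,
      subtitle = sprintf("slope %.3f, efficiency %.3f, R² %.4f",
                         object$slope, object$efficiency,
                         object$r_squared)) +
    ggplot2::theme_minimal()
}

#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  plot_metric_curve(object$curves)
}
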