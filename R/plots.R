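#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman difference plot
#'
#' Difference (alternative minus reference) against pair mean, with
#' horizontal lines at the median difference and the interquartile range.
#'
#' @param object A [bland_altman()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cr_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$cases, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$median, linetype = 1) +
    ggplot2::geom_hline(yintercept = object$iqr, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean of methods (mm)",
                  y = "difference, alternative - reference (mm)",
                  title = sprintf("Agreement: median %.2f (IQR %.2f, %.2f) mm",
                                  object$median, object$iqr[1], object$iqr[2])) +
    ggplot2::theme_minimal()
}

#' Accuracy distribution per technique
#'
#' Boxplots of the accuracy statistic by superimposition technique
#' (optionally faceted by operator).
#'
#' @param accuracy Accuracy tibble from [run_study()].
#' @param by_operator Facet by operator (default `FALSE`).
#' @return A ggplot.
#' @export
plot_accuracy <- function(accuracy, by_operator = FALSE) {
  p <- ggplot2::ggplot(accuracy,
                       ggplot2::aes(x = .data$technique, y = .data$D)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.5) +
    ggplot2::labs(x = "superimposition technique", y = "accuracy D (mm)") +
    ggplot2::theme_minimal()
  if (by_operator) p <- p + ggplot2::facet_wrap(~operator, labeller = ggplot2::label_both)
  p
}

#' Convergence history of an ICP run
#'
#' @param report An `icp_report` from [icp_point_to_plane()].
#' @param ... Unused.
#' @return A ggplot of trimmed RMS (log scale) per iteration.
#' @export
autoplot.icp_report <- function(report, ...) {
  df <- tibble::tibble(iteration = seq_along(report$rms_history),
                       rms = report$rms_history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$rms)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "trimmed RMS pair distance (mm)") +
    ggplot2::theme_minimal()
}
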