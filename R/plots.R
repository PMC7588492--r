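#' Forest plot of a metrics report
#'
#' One point plus 95% CI per metric, the CI already adjusted for
#' within-patient clustering via the design effect.
#'
#' @param object an `aki_metrics_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.aki_metrics_report <- function(object, ...) {
  d <- tidy.aki_metrics_report(object)
  d$metric <- factor(d$metric, levels = rev(d$metric))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$metric)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "estimate (95% CI, design-effect adjusted)",
                  y = NULL,
                  title = sprintf("ICC = %.2f, threshold = %.2f",
                                  d$icc[1], attr(object, "threshold"))) +
    ggplot2::theme_minimal()
}

#' Risk trajectory of one admission
#'
#' Per-step predicted AKI probability over the observation window, with
#' the decision threshold if supplied.
#'
#' @param predictions tibble from [predict_risk()] (one admission).
#' @param threshold optional decision threshold drawn as a dashed line.
#' @return a ggplot object.
#' @export
plot_risk_trajectory <- function(predictions, threshold = NULL) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$time_h, y = .data$risk)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "hours since admission", y = "predicted AKI risk") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Calibration curve from Hosmer-Lemeshow bins
#'
#' Observed event rate against mean predicted risk per decile bin; a
#' well-calibrated predictor tracks the diagonal.
#'
#' @param hl one-row result of [hosmer_lemeshow()].
#' @return a ggplot object.
#' @export
plot_calibration <- function(hl) {
  bins <- hl$bins[[1]]
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_risk,
                                     y = .data$obs_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "mean predicted risk", y = "observed AKI rate",
      title = sprintf("Hosmer-Lemeshow chi^2 = %.1f, df = %d, p = %.3g",
                      hl$statistic, hl$df, hl$p_value)) +
    ggplot2::theme_minimal()
}
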