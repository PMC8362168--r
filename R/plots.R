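# ggplot2 displays for bin tables, calibrators and experiments.

#' @describeIn bin_equal_size Reliability diagram of a bin table: mean
#'   predicted risk against observed event rate per bin, with the identity
#'   (perfect calibration) as reference.
#' @param object,x A `calibration_bins` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_bins <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p_mean, y = .data$o_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed event rate",
                  size = "Bin size") +
    ggplot2::theme_minimal()
}

#' @export
plot.calibration_bins <- function(x, ...) print(autoplot(x, ...))

plot_map <- function(object, label) {
  s <- seq(0, 1, length.out = 401)
  df <- tibble::tibble(score = s, calibrated = predict(object, s))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$calibrated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Initial score", y = "Calibrated probability",
                  title = label) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.platt_calibrator <- function(object, ...) {
  plot_map(object, "Platt scaling")
}

#' @exportS3Method ggplot2::autoplot
autoplot.isotonic_calibrator <- function(object, ...) {
  plot_map(object, "Isotonic regression (PAV)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rpr_calibrator <- function(object, ...) {
  plot_map(object, sprintf("Shape-restricted polynomial (k = %d, lambda = %g)",
                           object$degree, object$lambda))
}

#' @describeIn run_experiment Boxplots of a chosen metric over repetitions,
#'   one panel per base model, one box per calibration method.
#' @param object A `calibration_experiment`.
#' @param metric One of `"ece"`, `"mce"`, `"brier"`, `"auc"`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_experiment <- function(object, metric = "ece", ...) {
  metric <- match.arg(metric, c("ece", "mce", "brier", "auc"))
  df <- object$records
  df$calibration <- factor(df$calibration,
                           levels = c("raw", "platt", "isoreg", "rpr"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$calibration,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$model, nrow = 1) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' Histogram of test predictions per probability interval
#'
#' Bar chart of the median per-interval prediction counts of
#' [prediction_histogram()], one panel per model, bars by calibration
#' method.
#'
#' @param x A [run_experiment()] result.
#' @return A ggplot object.
#' @export
plot_prediction_histogram <- function(x) {
  h <- prediction_histogram(x)
  h$calibration <- factor(h$calibration,
                          levels = c("raw", "platt", "isoreg", "rpr"))
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$upper),
                                  y = .data$median_count,
                                  fill = .data$calibration)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$model) +
    ggplot2::labs(x = "Interval upper edge", y = "Median count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
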