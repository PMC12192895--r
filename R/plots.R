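#' Plot an ROC curve
#'
#' @param object A `roc_df` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_df <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot a hybrid ensemble's averaged curve
#'
#' @param object A `hybrid_result` from [run_hybrid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hybrid_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf(
        "Averaged hybrid ROC (%d trials): mean AUC = %.3f",
        object$iterations, object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Rater scatter with the human-mean benchmark and machine curve
#'
#' Reproduces the standard reader-study figure: every rater as a point in
#' ROC space, the unweighted mean of the panel as a highlighted benchmark
#' dot, and the machine's ROC curve behind them.
#'
#' @param report A `baseline_report` from [run_baseline()].
#' @return A ggplot object.
#' @export
plot_baseline <- function(report) {
  stopifnot(inherits(report, "baseline_report"))
  ggplot2::ggplot(report$rater_points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path(data = as_tibble(report$cnn_roc),
                       colour = "#2166ac") +
    ggplot2::geom_point(alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_point(data = report$mean_point, colour = "blue",
                        size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Rater panel vs machine baseline") +
    ggplot2::theme_minimal()
}
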