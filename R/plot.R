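METRIC_LABELS <- c(bias = "Bias (median residual, mL/min)",
                   precision = "Precision (residual IQR, mL/min)",
                   accuracy = "Accuracy (RMSE, mL/min)",
                   one_minus_p20 = "1-P20 (proportion)")

#' Four-panel performance plot of a model evaluation
#'
#' One panel per metric (bias, precision, accuracy, 1-P20) with point
#' estimates and 95% bootstrap error bars per model — the layout used in
#' multicenter eGFR validation figures.
#'
#' @param object A `gfr_evaluation` from [evaluate_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gfr_evaluation <- function(object, ...) {
  dat <- object$metrics
  dat$metric <- factor(dat$metric, levels = names(METRIC_LABELS),
                       labels = unname(METRIC_LABELS))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$model_id, y = .data$estimate)) +
    ggplot2::geom_hline(
      data = data.frame(metric = METRIC_LABELS[["bias"]], y = 0),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)) +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Model performance (n = %d, %d bootstrap reps)",
                                  object$n, object$reps)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot.gfr_evaluation
#' @param evaluation A `gfr_evaluation`.
#' @export
plot_metric_panel <- function(evaluation, ...) autoplot.gfr_evaluation(evaluation, ...)
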