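# ggplot2 views of training and evaluation results.

#' Plot a training log
#'
#' Per-batch L1 loss with the sliding-window mean overlaid; the best window
#' (the returned snapshot) is marked.
#'
#' @param object a `purity_training_log` tibble (`model$training_log`).
#' @param ... unused.
#' @export
#' @method autoplot purity_training_log
autoplot.purity_training_log <- function(object, ...) {
  best <- object[which.min(object$window_mean), ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$batch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$window_mean), colour = "#2166ac",
                       linewidth = 0.7, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = best$batch, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = "batch", y = "L1 loss",
                  title = "Training loss",
                  subtitle = sprintf("best sliding-window mean %.4f at batch %d",
                                     best$window_mean, best$batch)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation
#'
#' Predicted vs true purity with the identity line; the subtitle reports the
#' four metrics.
#'
#' @param object a `purity_evaluation`.
#' @param ... unused.
#' @export
#' @method autoplot purity_evaluation
autoplot.purity_evaluation <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$truth, y = .data$purity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, colour = "#2166ac") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "true purity", y = "predicted purity",
                  title = m$dataset,
                  subtitle = sprintf("n=%d  MAE=%.3f  RMSE=%.3f  r=%.3f  CCC=%.3f",
                                     m$n, m$mae, m$rmse, m$pearson, m$ccc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.purity_training_log
#' @param model a trained `purity_model`.
#' @export
plot_training <- function(model, ...) {
  stopifnot(inherits(model, "purity_model"), !is.null(model$training_log))
  autoplot(model$training_log, ...)
}

#' @rdname autoplot.purity_evaluation
#' @param evaluation a `purity_evaluation`.
#' @export
plot_evaluation <- function(evaluation, ...) autoplot(evaluation, ...)
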