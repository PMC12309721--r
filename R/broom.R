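# broom-style accessors for the package's result objects.

#' Tidy a purity model
#'
#' One row per layer with its dimensions and parameter count.
#'
#' @param x a `purity_model`.
#' @param ... unused.
#' @export
#' @method tidy purity_model
tidy.purity_model <- function(x, ...) {
  dims <- c(length(x$feature_ids), x$config$hidden_sizes, 1L)
  tibble(layer = seq_along(x$layers),
         input_dim = dims[-length(dims)],
         output_dim = dims[-1],
         activation = c(rep("relu", length(x$layers) - 1L), "linear"),
         n_parameters = vapply(x$layers, function(l) length(l$W) + length(l$b),
                               numeric(1)))
}

#' Glance at a purity model
#'
#' One-row training summary: feature count, parameter count, batches run,
#' best sliding-window loss and stop reason.
#'
#' @param x a `purity_model`.
#' @param ... unused.
#' @export
#' @method glance purity_model
glance.purity_model <- function(x, ...) {
  tr <- x$training
  tibble(n_features = length(x$feature_ids),
         n_parameters = n_parameters(x),
         n_batches = tr$n_batches %||% NA_integer_,
         best_batch = tr$best_batch %||% NA_integer_,
         best_window_mean = tr$best_window_mean %||% NA_real_,
         stop_reason = tr$stop_reason %||% "untrained")
}

#' Per-sample rows of an evaluation
#' @param x a `purity_evaluation`.
#' @param ... unused.
#' @export
#' @method tidy purity_evaluation
tidy.purity_evaluation <- function(x, ...) x$samples

#' One-row metric summary of an evaluation
#' @param x a `purity_evaluation`.
#' @param ... unused.
#' @export
#' @method glance purity_evaluation
glance.purity_evaluation <- function(x, ...) x$metrics

#' Tidy a feature selection
#'
#' The per-gene KS report (gene id, D statistic, retained flag).
#'
#' @param x a `feature_selection`.
#' @param ... unused.
#' @export
#' @method tidy feature_selection
tidy.feature_selection <- function(x, ...) x$ks_report

#' Stage counts of a feature selection
#' @param x a `feature_selection`.
#' @param ... unused.
#' @export
#' @method glance feature_selection
glance.feature_selection <- function(x, ...) {
  tidyr::pivot_wider(x$stages, names_from = "stage", values_from = "n_genes")
}
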