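# Evaluation metrics for predicted vs true purity: MAE, RMSE, Pearson
# correlation, and Lin's concordance correlation coefficient with population
# (1/n) moments.

check_pair <- function(y, yhat, min_n = 1L) {
  if (length(y) != length(yhat)) abort("length mismatch between y and yhat")
  if (length(y) < min_n) abort(sprintf("need at least %d observations", min_n))
  if (anyNA(y) || anyNA(yhat)) abort("metrics require complete inputs")
  invisible(NULL)
}

#' Mean absolute error
#' @param y true values.
#' @param yhat predicted values.
#' @export
mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(y - yhat))
}

#' Root mean squared error
#' @inheritParams mae
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation
#'
#' Product-moment correlation; undefined (an error) when either vector is
#' constant. Batch reports catch the error and record `NA`.
#'
#' @inheritParams mae
#' @export
pearson <- function(y, yhat) {
  check_pair(y, yhat, min_n = 2L)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    abort("pearson correlation is undefined for a constant vector")
  }
  stats::cor(y, yhat)
}

#' Concordance correlation coefficient
#'
#' Lin's CCC, `2*s_xy / (s_x^2 + s_y^2 + (mean(y) - mean(yhat))^2)` with
#' population (1/n) variances and covariance. Penalises location and scale
#' shift as well as scatter; `|CCC| <= |Pearson|` always.
#'
#' @inheritParams mae
#' @export
ccc <- function(y, yhat) {
  check_pair(y, yhat, min_n = 2L)
  n <- length(y)
  my <- mean(y)
  mp <- mean(yhat)
  vy <- mean((y - my)^2)
  vp <- mean((yhat - mp)^2)
  cov <- mean((y - my) * (yhat - mp))
  denom <- vy + vp + (my - mp)^2
  if (denom == 0) abort("ccc is undefined: both vectors constant with equal means")
  2 * cov / denom
}

#' Evaluate a purity model on labeled pseudobulks
#'
#' Predicts purity for every column of `pseudobulks` and compares against the
#' true labels with all four metrics. Correlations on fewer than two samples
#' or constant vectors are reported as `NA` with a warning.
#'
#' @param model a trained `purity_model`.
#' @param pseudobulks genes x samples raw count matrix.
#' @param labels true purity per column, aligned to `colnames(pseudobulks)`
#'   (or named by them).
#' @param lengths gene lengths for the input transform.
#' @param dataset_name label carried into the report.
#' @param ... passed on to [predict.purity_model()].
#' @return object of class `purity_evaluation` with `$samples` (per-sample
#'   tibble) and `$metrics` (one-row tibble: dataset, n, mae, rmse, pearson,
#'   ccc).
#' @export
evaluate_purity <- function(model, pseudobulks, labels, lengths,
                            dataset_name = "dataset", ...) {
  pseudobulks <- as_count_matrix(pseudobulks)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(pseudobulks))) {
      abort("label names do not match pseudobulk columns")
    }
    labels <- labels[colnames(pseudobulks)]
  }
  if (length(labels) != ncol(pseudobulks)) {
    abort("need one purity label per pseudobulk column")
  }
  pred <- predict(model, pseudobulks, lengths, ...)
  samples <- dplyr::mutate(pred, truth = as.numeric(labels), .after = "sample_id")
  safe_cor <- function(f, name) {
    tryCatch(f(samples$truth, samples$purity), error = function(e) {
      warn(sprintf("%s reported as NA: %s", name, conditionMessage(e)))
      NA_real_
    })
  }
  metrics <- tibble(
    dataset = dataset_name,
    n = nrow(samples),
    mae = mae(samples$truth, samples$purity),
    rmse = rmse(samples$truth, samples$purity),
    pearson = if (nrow(samples) >= 2) safe_cor(pearson, "pearson") else NA_real_,
    ccc = if (nrow(samples) >= 2) safe_cor(ccc, "ccc") else NA_real_
  )
  structure(list(samples = samples, metrics = metrics),
            class = "purity_evaluation")
}

#' @export
print.purity_evaluation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<purity_evaluation> %s: n=%d  MAE=%.3f  RMSE=%.3f  r=%.3f  CCC=%.3f\n",
              m$dataset, m$n, m$mae, m$rmse, m$pearson, m$ccc))
  invisible(x)
}
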