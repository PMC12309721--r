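# On-the-fly simulation of labeled pseudobulk tumors. Each simulated tumor
# draws cells with replacement from a single corpus sample only, preserving
# inter-patient heterogeneity; its ground-truth purity is the realized
# malignant fraction Nm / N, not the target p.
#
# RNG draw order (replayable with a fixed seed):
#   per tumor: sample index -> p ~ U(purity_min, purity_max)
#              -> N ~ discrete U{cells_min..cells_max}
#              -> Nm malignant cell indices (sample.int, with replacement)
#              -> Nn nonmalignant cell indices (sample.int, with replacement)
#   simulate_pseudobulk() performs only the two cell-index draws.

#' Simulation configuration
#'
#' Ranges for the two random numbers drawn per simulated tumor — the target
#' purity p and the number of cells N — plus the per-class eligibility floor.
#'
#' @param purity_min,purity_max target purity range (default 0–1, uniform).
#' @param cells_min,cells_max range of the number of cells per simulated
#'   tumor (default 200–4000, discrete uniform).
#' @param min_cells_per_class samples with fewer malignant or nonmalignant
#'   cells than this are excluded from simulation (default 5).
#' @param batch_size simulated tumors per training batch (default 64).
#' @export
simulation_config <- function(purity_min = 0, purity_max = 1,
                              cells_min = 200, cells_max = 4000,
                              min_cells_per_class = 5, batch_size = 64) {
  stopifnot(purity_min >= 0, purity_max <= 1, purity_min <= purity_max,
            cells_min >= 1, cells_min <= cells_max,
            min_cells_per_class >= 1, batch_size >= 1)
  structure(list(purity_min = purity_min, purity_max = purity_max,
                 cells_min = as.integer(cells_min), cells_max = as.integer(cells_max),
                 min_cells_per_class = as.integer(min_cells_per_class),
                 batch_size = as.integer(batch_size)),
            class = "simulation_config")
}

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Split a corpus into per-sample malignant / nonmalignant count submatrices
# once, so repeated simulation does no data-frame work in the hot loop.
corpus_class_split <- function(corpus, sample_ids = NULL) {
  sample_ids <- sample_ids %||% unique(corpus$cells$sample_id)
  split <- lapply(sample_ids, function(s) {
    in_sample <- corpus$cells$sample_id == s
    mal <- corpus$cells$cell_id[in_sample & corpus$cells$label == "malignant"]
    non <- corpus$cells$cell_id[in_sample & corpus$cells$label == "nonmalignant"]
    list(mal = corpus$counts[, mal, drop = FALSE],
         non = corpus$counts[, non, drop = FALSE])
  })
  names(split) <- sample_ids
  split
}

draw_pseudobulk_counts <- function(split_entry, p, N) {
  n_mal <- ncol(split_entry$mal)
  n_non <- ncol(split_entry$non)
  Nm <- as.integer(round_half_away(p * N))
  Nn <- N - Nm
  counts <- numeric(nrow(split_entry$mal))
  if (Nm > 0) {
    idx <- sample.int(n_mal, Nm, replace = TRUE)
    counts <- counts + drop(split_entry$mal %*% tabulate(idx, n_mal))
  }
  if (Nn > 0) {
    idx <- sample.int(n_non, Nn, replace = TRUE)
    counts <- counts + drop(split_entry$non %*% tabulate(idx, n_non))
  }
  list(counts = counts, Nm = Nm, Nn = Nn)
}

#' Simulate one labeled pseudobulk tumor
#'
#' Draws `Nm = round(p * N)` malignant and `Nn = N - Nm` nonmalignant cells
#' uniformly with replacement from one sample of the corpus and sums their
#' count vectors. The purity label is the realized malignant fraction
#' `Nm / N` (which differs from the target `p` by at most `0.5 / N`).
#'
#' @param corpus a [single_cell_corpus()].
#' @param sample_id the sample to draw from; must be eligible under
#'   `min_cells_per_class`.
#' @param p target purity in \[0, 1\].
#' @param N number of cells to draw.
#' @param min_cells_per_class eligibility floor (default 5).
#' @return object of class `labeled_pseudobulk`: `counts` (named vector over
#'   genes), `purity`, `sample_id`, `n_cells`, `n_malignant`.
#' @export
simulate_pseudobulk <- function(corpus, sample_id, p, N, min_cells_per_class = 5) {
  stopifnot(inherits(corpus, "single_cell_corpus"),
            p >= 0, p <= 1, N >= 1)
  if (!sample_id %in% eligible_samples(corpus, min_cells_per_class)) {
    abort(sprintf("sample '%s' is not eligible (needs >= %d cells of each class)",
                  sample_id, min_cells_per_class))
  }
  split <- corpus_class_split(corpus, sample_id)[[1]]
  drawn <- draw_pseudobulk_counts(split, p, as.integer(N))
  structure(list(counts = setNames(drawn$counts, rownames(corpus$counts)),
                 purity = drawn$Nm / N,
                 sample_id = sample_id,
                 n_cells = as.integer(N),
                 n_malignant = drawn$Nm),
            class = "labeled_pseudobulk")
}

#' @export
print.labeled_pseudobulk <- function(x, ...) {
  cat(sprintf("<labeled_pseudobulk> sample %s, %d cells, purity %.3f\n",
              x$sample_id, x$n_cells, x$purity))
  invisible(x)
}

#' Simulate a training batch of pseudobulk tumors
#'
#' For each of `batch_size` tumors: a corpus sample is chosen uniformly among
#' eligible samples, p and N are drawn from the configured ranges, a
#' pseudobulk is simulated within that sample, and the result is mapped into
#' model-input space against the feature set.
#'
#' @param corpus a [single_cell_corpus()].
#' @param features the model's [feature_set()].
#' @param lengths gene lengths covering the corpus genes (TPM step).
#' @param config a [simulation_config()].
#' @return list with `x` (batch_size x |features| model-input matrix),
#'   `purity` (exact realized labels), and `sample_id`.
#' @export
simulate_batch <- function(corpus, features, lengths, config = simulation_config()) {
  stopifnot(inherits(corpus, "single_cell_corpus"),
            inherits(config, "simulation_config"))
  eligible <- eligible_samples(corpus, config$min_cells_per_class)
  split <- corpus_class_split(corpus, eligible)
  simulate_batch_presplit(split, rownames(corpus$counts), features, lengths, config)
}

# Hot-loop variant used by the trainer: the per-sample class split is done
# once outside the training loop.
simulate_batch_presplit <- function(split, gene_ids, features, lengths, config) {
  b <- config$batch_size
  raw <- matrix(0, nrow = length(gene_ids), ncol = b,
                dimnames = list(gene_ids, paste0("sim", seq_len(b))))
  purity <- numeric(b)
  sample_id <- character(b)
  span <- config$cells_max - config$cells_min + 1L
  for (i in seq_len(b)) {
    s <- sample.int(length(split), 1L)
    p <- runif(1, config$purity_min, config$purity_max)
    N <- config$cells_min + sample.int(span, 1L) - 1L
    drawn <- draw_pseudobulk_counts(split[[s]], p, N)
    raw[, i] <- drawn$counts
    purity[i] <- drawn$Nm / N
    sample_id[i] <- names(split)[s]
  }
  transformed <- model_input_transform(raw, features, lengths, strip_versions = FALSE)
  list(x = t(transformed$values), purity = purity, sample_id = sample_id)
}
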