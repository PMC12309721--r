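# The training substrate: a genes x cells raw count matrix plus one sample id
# and one malignant/nonmalignant label per cell.

#' Construct a labeled single-cell corpus
#'
#' @param counts genes x cells raw count matrix (cells as columns).
#' @param cells data frame with columns `cell_id`, `sample_id`, `label`
#'   (values `"malignant"` or `"nonmalignant"`), one row per column of
#'   `counts`.
#' @return object of class `single_cell_corpus`.
#' @export
single_cell_corpus <- function(counts, cells) {
  counts <- as_count_matrix(counts)
  cells <- as_tibble(cells)
  required <- c("cell_id", "sample_id", "label")
  if (!all(required %in% names(cells))) {
    abort(sprintf("cell annotations need columns: %s", paste(required, collapse = ", ")))
  }
  cells <- dplyr::mutate(cells, dplyr::across(dplyr::all_of(required), as.character))
  if (anyDuplicated(cells$cell_id)) abort("duplicate cell ids in annotation")
  if (!setequal(cells$cell_id, colnames(counts)) ||
      nrow(cells) != ncol(counts)) {
    abort("cell annotation ids must match count matrix columns exactly")
  }
  bad <- setdiff(unique(cells$label), c("malignant", "nonmalignant"))
  if (length(bad)) {
    abort(sprintf("cell labels must be malignant/nonmalignant; found: %s",
                  paste(bad, collapse = ", ")))
  }
  if (anyNA(cells$sample_id)) abort("every cell needs a sample id")
  cells <- cells[match(colnames(counts), cells$cell_id), ]
  structure(list(counts = counts, cells = cells), class = "single_cell_corpus")
}

#' @export
print.single_cell_corpus <- function(x, ...) {
  cat(sprintf("<single_cell_corpus> %d genes x %d cells, %d samples (%.0f%% malignant)\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$cells$sample_id),
              100 * mean(x$cells$label == "malignant")))
  invisible(x)
}

#' Read cell annotations from TSV
#'
#' Columns: `cell_id`, `sample_id`, `label` in \{malignant, nonmalignant\}.
#'
#' @param path TSV file.
#' @export
read_cell_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_tibble(df)
}

#' Per-sample pseudobulks of a corpus
#'
#' Sums the count vectors of all cells belonging to each sample; the purity
#' label of a pseudobulk is the malignant fraction among that sample's cells.
#'
#' @param corpus a [single_cell_corpus()].
#' @return list with `counts` (genes x samples matrix, one column per sample)
#'   and `samples`, a tibble with `sample_id`, `n_cells`, `n_malignant`,
#'   `purity`.
#' @export
pseudobulk_per_sample <- function(corpus) {
  stopifnot(inherits(corpus, "single_cell_corpus"))
  sample_ids <- unique(corpus$cells$sample_id)
  f <- factor(corpus$cells$sample_id, levels = sample_ids)
  # genes x samples: sum cell columns within sample via group indicator
  indicator <- outer_indicator(f)
  counts <- corpus$counts %*% indicator
  colnames(counts) <- sample_ids
  samples <- corpus$cells |>
    dplyr::group_by(sample_id = .data$sample_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_malignant = sum(.data$label == "malignant"),
                     purity = mean(.data$label == "malignant"),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$sample_id, sample_ids))
  list(counts = counts, samples = samples)
}

outer_indicator <- function(f) {
  ind <- matrix(0, nrow = length(f), ncol = nlevels(f))
  ind[cbind(seq_along(f), as.integer(f))] <- 1
  ind
}

#' Samples eligible for purity simulation
#'
#' A sample qualifies only with at least `min_cells_per_class` malignant and
#' at least that many nonmalignant cells, so both classes can be drawn across
#' the whole purity range.
#'
#' @param corpus a [single_cell_corpus()].
#' @param min_cells_per_class minimum cells of each class (default 5).
#' @return character vector of eligible sample ids.
#' @export
eligible_samples <- function(corpus, min_cells_per_class = 5) {
  stopifnot(inherits(corpus, "single_cell_corpus"))
  tab <- corpus$cells |>
    dplyr::count(.data$sample_id, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n", values_fill = 0L)
  if (!"malignant" %in% names(tab)) tab$malignant <- 0L
  if (!"nonmalignant" %in% names(tab)) tab$nonmalignant <- 0L
  ok <- tab$malignant >= min_cells_per_class & tab$nonmalignant >= min_cells_per_class
  out <- tab$sample_id[ok]
  if (!length(out)) abort("no sample eligible for simulation")
  out[order(match(out, unique(corpus$cells$sample_id)))]
}
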