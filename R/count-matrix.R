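# Count matrices are plain numeric matrices: genes as rows (rownames = gene
# ids), samples or cells as columns (colnames = column ids). Validation is
# centralised here so every entry point enforces the same contract.

#' Validate or coerce a raw count matrix
#'
#' Accepts a numeric matrix (genes as rows) or a data frame whose first column
#' holds gene identifiers and remaining columns hold per-sample counts, and
#' returns a validated numeric matrix with gene ids as rownames.
#'
#' @param x matrix or data.frame of raw counts.
#' @param transpose if `TRUE`, the input is columns-as-genes and is transposed
#'   before validation.
#' @return numeric matrix, genes x columns, with unique dimnames.
#' @export
as_count_matrix <- function(x, transpose = FALSE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("counts must be a numeric matrix or a data frame with gene ids in column 1")
  }
  if (transpose) x <- t(x)
  validate_count_matrix(x)
  x
}

validate_count_matrix <- function(m, what = "count matrix") {
  if (nrow(m) < 1L || ncol(m) < 1L) {
    abort(sprintf("%s must have at least one gene and one column", what))
  }
  if (is.null(rownames(m))) abort(sprintf("%s must carry gene ids as rownames", what))
  if (is.null(colnames(m))) abort(sprintf("%s must carry column ids as colnames", what))
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    abort(sprintf("duplicate gene ids: %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    abort(sprintf("duplicate column ids: %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyNA(m) || any(!is.finite(m))) abort(sprintf("%s contains missing or non-finite values", what))
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at gene '%s', column '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  invisible(m)
}

#' Read a raw count matrix from disk
#'
#' Dense TSV/CSV files carry a header row of column ids and gene ids in the
#' first column. A MatrixMarket triplet directory (CellRanger style) holds a
#' coordinate `.mtx` file plus `features.tsv`/`genes.tsv` and `barcodes.tsv`.
#'
#' @param path file (dense) or directory (MTX triplet).
#' @param format `"auto"` (default, inferred from the path), `"tsv"`, `"csv"`,
#'   or `"mtx"`.
#' @param transpose treat dense input as columns-as-genes.
#' @return numeric matrix, genes x columns.
#' @export
read_count_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"), transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
    else "tsv"
  }
  if (format == "mtx") return(read_mtx_dir(path))
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  # base read.delim: strtod parsing is correctly rounded, so full-precision
  # decimal text round-trips bit-for-bit (readr's fast parser does not)
  df <- tryCatch(
    utils::read.delim(path, sep = if (format == "csv") "," else "\t",
                      header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
  )
  if (ncol(df) < 2L) abort(sprintf("%s: need a gene-id column plus at least one count column", path))
  num <- df[, -1, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(num)[bad][1]
    row <- which(is.na(suppressWarnings(as.numeric(num[[col]]))))[1]
    abort(sprintf("%s: non-numeric value in column '%s' near line %d",
                  path, col, (row %||% 1L) + 1L))
  }
  as_count_matrix(as.data.frame(df), transpose = transpose)
}

read_mtx_dir <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("directory not found: %s", dir))
  mtx <- first_existing(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- first_existing(dir, c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc <- first_existing(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- as.matrix(Matrix::readMM(mtx))
  features <- readr::read_tsv(feat, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_tsv(bc, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  if (nrow(features) != nrow(m)) abort("feature list length does not match matrix rows")
  if (nrow(barcodes) != ncol(m)) abort("barcode list length does not match matrix columns")
  rownames(m) <- as.character(features[[1]])
  colnames(m) <- as.character(barcodes[[1]])
  validate_count_matrix(m)
  m
}

first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  abort(sprintf("none of %s found in %s", paste(names, collapse = "/"), dir))
}

#' Write a count matrix as dense TSV
#'
#' Writes gene ids in a `gene_id` first column; numeric values use full
#' precision so a read round-trip reproduces the matrix bit-for-bit.
#'
#' @param m genes x columns matrix.
#' @param path output file.
#' @export
write_count_matrix <- function(m, path) {
  validate_count_matrix(m)
  # %.17g guarantees the decimal text parses back to the identical double
  formatted <- tibble::as_tibble(matrix(sprintf("%.17g", m), nrow(m),
                                        dimnames = dimnames(m)))
  readr::write_tsv(dplyr::bind_cols(tibble(gene_id = rownames(m)), formatted),
                   path, progress = FALSE)
  invisible(path)
}

#' Read a gene-length table
#'
#' Two-column TSV: gene id and length in bases. Lengths must be positive.
#'
#' @param path TSV file.
#' @return named numeric vector of lengths, names are gene ids.
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) abort("gene length table needs two columns: gene_id, length")
  as_gene_lengths(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
}

as_gene_lengths <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- setNames(as.numeric(lengths[[2]]), as.character(lengths[[1]]))
  if (is.null(names(lengths)) || anyNA(lengths)) abort("gene lengths must be a named numeric vector")
  if (any(lengths <= 0)) {
    abort(sprintf("non-positive gene lengths: %s",
                  paste(head(names(lengths)[lengths <= 0], 5), collapse = ", ")))
  }
  if (anyDuplicated(names(lengths))) abort("duplicate gene ids in gene lengths")
  lengths
}

#' Strip Ensembl-style version suffixes from gene ids
#'
#' `ENSG00000141510.17` becomes `ENSG00000141510`. Identifier matching across
#' cohorts is exact string match after this normalisation (can be disabled
#' wherever it is applied).
#'
#' @param ids character vector of gene ids.
#' @export
strip_gene_versions <- function(ids) {
  sub("\\.\\d+$", "", ids)
}
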