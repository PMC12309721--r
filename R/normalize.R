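# Library-size normalisations and the model-input transform.
#
# CPM_ij = x_ij / sum_k x_kj * 1e6
# TPM_ij = (x_ij / l_i) / sum_k (x_kj / l_k) * 1e6
# model input = log2(TPM / 100 + 1), rows subset/reordered to a feature set.

#' Counts-per-million normalisation
#'
#' Scales every column so its values sum to one million.
#'
#' @param m genes x columns raw count matrix.
#' @return matrix of the same shape; attribute `scheme` is `"CPM"`.
#' @export
cpm_normalize <- function(m) {
  m <- as_count_matrix(m)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("zero total count in column(s): %s",
                  paste(head(colnames(m)[totals == 0], 5), collapse = ", ")))
  }
  out <- sweep(m, 2, totals, "/") * 1e6
  attr(out, "scheme") <- "CPM"
  out
}

#' Transcripts-per-million normalisation
#'
#' Divides counts by gene length (bases) before library-size scaling, so that
#' columns sum to one million in length-corrected units.
#'
#' @param m genes x columns raw count matrix.
#' @param lengths named numeric vector (or two-column data frame) of gene
#'   lengths covering every gene in `m`.
#' @return matrix of the same shape; attribute `scheme` is `"TPM"`.
#' @export
tpm_normalize <- function(m, lengths) {
  m <- as_count_matrix(m)
  lengths <- as_gene_lengths(lengths)
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing)) {
    abort(sprintf("no length for %d gene(s): %s%s", length(missing),
                  paste(head(missing, 5), collapse = ", "),
                  if (length(missing) > 5) ", ..." else ""))
  }
  rate <- m / lengths[rownames(m)]
  totals <- colSums(rate)
  if (any(totals == 0)) {
    abort(sprintf("zero length-normalized total in column(s): %s",
                  paste(head(colnames(m)[totals == 0], 5), collapse = ", ")))
  }
  out <- sweep(rate, 2, totals, "/") * 1e6
  attr(out, "scheme") <- "TPM"
  out
}

#' Transform raw counts into model-input space
#'
#' TPM is computed on the full input matrix (all genes present), the rows are
#' then subset and reordered to exactly the feature set, genes absent from the
#' input are zero-filled, and values become `log2(TPM / 100 + 1)`. The
#' fraction of feature genes absent from the input drives the missing-gene
#' guards at prediction time.
#'
#' @param m genes x columns raw count matrix.
#' @param features a [feature_set()] or character vector of gene ids.
#' @param lengths gene lengths covering the genes in `m`.
#' @param strip_versions strip Ensembl version suffixes from the input gene
#'   ids before matching (default `TRUE`).
#' @return list with `values` (|features| x columns matrix, attribute `scheme`
#'   = `"MODEL_INPUT"`), `missing_genes`, and `missing_fraction`.
#' @export
model_input_transform <- function(m, features, lengths, strip_versions = TRUE) {
  ids <- feature_ids(features)
  m <- as_count_matrix(m)
  if (strip_versions) {
    stripped <- strip_gene_versions(rownames(m))
    if (!anyDuplicated(stripped)) rownames(m) <- stripped
  }
  tpm <- tpm_normalize(m, lengths)
  missing <- setdiff(ids, rownames(tpm))
  values <- matrix(0, nrow = length(ids), ncol = ncol(m),
                   dimnames = list(ids, colnames(m)))
  present <- intersect(ids, rownames(tpm))
  values[present, ] <- tpm[present, , drop = FALSE]
  values <- log2(values / 100 + 1)
  attr(values, "scheme") <- "MODEL_INPUT"
  list(values = values,
       missing_genes = missing,
       missing_fraction = length(missing) / length(ids))
}
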