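# Independent brute-force oracles and tiny fixture builders shared by the
# suite. Oracles are written from the definitions, never from the package's
# implementation paths.

# KS distance by direct enumeration of both ECDFs over every observed value.
oracle_ks <- function(a, b) {
  values <- sort(unique(c(a, b)))
  max(abs(vapply(values, function(v) mean(a <= v) - mean(b <= v), numeric(1))))
}

oracle_mae <- function(y, yhat) sum(abs(y - yhat)) / length(y)

oracle_rmse <- function(y, yhat) sqrt(sum((y - yhat)^2) / length(y))

oracle_pearson <- function(y, yhat) {
  num <- sum((y - mean(y)) * (yhat - mean(yhat)))
  num / sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
}

# Lin's concordance with population (1/n) moments, straight from the moments.
oracle_ccc <- function(y, yhat) {
  n <- length(y)
  sxy <- sum((y - mean(y)) * (yhat - mean(yhat))) / n
  sx <- sum((y - mean(y))^2) / n
  sy <- sum((yhat - mean(yhat))^2) / n
  2 * sxy / (sx + sy + (mean(y) - mean(yhat))^2)
}

oracle_cpm <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- m[, j] / sum(m[, j]) * 1e6
  out
}

oracle_tpm <- function(m, lengths) {
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- m[, j] / lengths[rownames(m)]
    out[, j] <- r / sum(r) * 1e6
  }
  out
}

# A small fully explicit corpus: `spec` is a list of per-sample lists with
# elements mal (genes x cells matrix) and non.
make_corpus <- function(spec, gene_ids) {
  counts <- NULL
  cells <- NULL
  for (s in names(spec)) {
    for (lab in c("mal", "non")) {
      m <- spec[[s]][[lab]]
      if (is.null(m) || !ncol(m)) next
      colnames(m) <- sprintf("%s_%s%02d", s, lab, seq_len(ncol(m)))
      rownames(m) <- gene_ids
      counts <- cbind(counts, m)
      cells <- rbind(cells, data.frame(
        cell_id = colnames(m), sample_id = s,
        label = if (lab == "mal") "malignant" else "nonmalignant"))
    }
  }
  single_cell_corpus(counts, cells)
}

# Random valid count matrix for property tests.
random_counts <- function(n_genes = 6, n_cols = 4, max_count = 50) {
  m <- matrix(sample.int(max_count, n_genes * n_cols, replace = TRUE),
              n_genes, n_cols,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_cols))))
  storage.mode(m) <- "double"
  m
}

random_lengths <- function(gene_ids) {
  setNames(sample(200:5000, length(gene_ids), replace = TRUE), gene_ids)
}

# Corpus with one private marker gene per sample: any cross-sample leakage in
# the simulator shows up as counts on a foreign marker.
private_marker_corpus <- function(n_samples = 3, cells_per_class = 6) {
  gene_ids <- c(sprintf("marker_%d", seq_len(n_samples)), "house1", "house2")
  spec <- list()
  for (i in seq_len(n_samples)) {
    base <- matrix(5, length(gene_ids), cells_per_class)
    base[seq_len(n_samples), ] <- 0
    base[i, ] <- 50
    mal <- base
    non <- base
    mal[length(gene_ids) - 1, ] <- 30   # house1 up in malignant cells
    non[length(gene_ids), ] <- 30       # house2 up in nonmalignant cells
    spec[[sprintf("P%d", i)]] <- list(mal = mal, non = non)
  }
  make_corpus(spec, gene_ids)
}
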