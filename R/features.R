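# Cross-modality feature selection: genes must be (a) prevalent in both bulk
# and pseudobulk cohorts (CPM >= 1 in more than half the samples of each) and
# (b) similarly distributed across modalities (two-sample KS statistic D on
# CPM values at most 0.4). The surviving, ordered gene list is frozen into a
# feature set that fixes the model's input dimension.

#' Construct a feature set
#'
#' An ordered, unique gene list plus the provenance of its selection. The
#' order is fixed at training time and defines the model input layout.
#'
#' @param gene_ids character vector, non-empty, unique.
#' @param provenance named list recording selection parameters and cohort
#'   sizes.
#' @export
feature_set <- function(gene_ids, provenance = list()) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) abort("a feature set cannot be empty")
  if (anyDuplicated(gene_ids)) abort("feature set gene ids must be unique")
  structure(list(gene_ids = gene_ids, provenance = provenance),
            class = "feature_set")
}

feature_ids <- function(features) {
  if (inherits(features, "feature_set")) features$gene_ids
  else if (is.character(features) && length(features)) unname(features)
  else abort("features must be a feature_set or a character vector of gene ids")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes\n", length(x$gene_ids)))
  if (length(x$provenance)) {
    p <- x$provenance
    cat("  provenance:", paste(names(p), unlist(lapply(p, format)),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$gene_ids)

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Exact supremum distance `D = sup_x |F_a(x) - F_b(x)|` between the two
#' empirical distribution functions, computed by breakpoint enumeration over
#' the merged sorted values (ties handled exactly). No asymptotic
#' approximation and no p-value: the screen uses the distance only.
#'
#' @param a,b non-empty numeric vectors.
#' @return D in \[0, 1\]; symmetric in its arguments.
#' @export
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) abort("ks_statistic: both samples must be non-empty")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    abort("ks_statistic: inputs must be finite")
  }
  n1 <- length(a)
  n2 <- length(b)
  w <- c(a, b)
  ord <- order(w)
  steps <- ifelse(ord <= n1, 1 / n1, -1 / n2)
  gap <- cumsum(steps)
  ws <- w[ord]
  # evaluate |F_a - F_b| only after all ties at a value are consumed
  last_of_tie <- c(ws[-1] != ws[-length(ws)], TRUE)
  max(abs(gap[last_of_tie]))
}

#' Prevalence filter on CPM values
#'
#' A gene is excluded when, in either modality, the proportion of samples with
#' CPM below `cpm_threshold` is at least `fraction`. Gene universes are
#' intersected first; an empty intersection is an error.
#'
#' @param bulk_cpm,pseudo_cpm CPM-normalised matrices (see [cpm_normalize()]).
#' @param cpm_threshold expression floor in CPM units (default 1).
#' @param fraction exclusion boundary on the low-expression sample proportion
#'   (default 0.5; a gene sitting exactly at the boundary is excluded).
#' @return character vector of retained gene ids, in `pseudo_cpm` row order.
#' @export
prevalence_filter <- function(bulk_cpm, pseudo_cpm, cpm_threshold = 1, fraction = 0.5) {
  common <- intersect(rownames(pseudo_cpm), rownames(bulk_cpm))
  if (!length(common)) abort("no genes shared between the bulk and pseudobulk matrices")
  low_bulk <- rowMeans(bulk_cpm[common, , drop = FALSE] < cpm_threshold)
  low_pseudo <- rowMeans(pseudo_cpm[common, , drop = FALSE] < cpm_threshold)
  common[low_bulk < fraction & low_pseudo < fraction]
}

#' Select cross-modality-consistent genes
#'
#' CPM-normalises a bulk cohort and a per-sample pseudobulk matrix of the
#' training corpus, applies the prevalence filter, then screens each surviving
#' gene with the two-sample KS statistic between its CPM values across bulk
#' samples and across pseudobulk samples, retaining genes with
#' `D <= ks_threshold`. The resulting feature-set order follows the pseudobulk
#' input gene order.
#'
#' @param bulk genes x samples raw bulk count matrix.
#' @param sc_pseudobulks genes x samples raw per-sample pseudobulk matrix
#'   (one column per corpus sample; see [pseudobulk_per_sample()]).
#' @param cpm_threshold,fraction prevalence-filter parameters.
#' @param ks_threshold maximum KS distance retained (default 0.4).
#' @param strip_versions strip Ensembl version suffixes before intersecting
#'   gene universes.
#' @param verbose log retained-gene counts at each stage.
#' @return object of class `feature_selection`: `feature_set`, a `ks_report`
#'   tibble (gene_id, D, retained), and a `stages` tibble of gene counts.
#' @export
select_features <- function(bulk, sc_pseudobulks, cpm_threshold = 1, fraction = 0.5,
                            ks_threshold = 0.4, strip_versions = TRUE,
                            verbose = FALSE) {
  bulk <- as_count_matrix(bulk)
  sc_pseudobulks <- as_count_matrix(sc_pseudobulks)
  if (strip_versions) {
    for (nm in c("bulk", "sc_pseudobulks")) {
      m <- get(nm)
      stripped <- strip_gene_versions(rownames(m))
      if (!anyDuplicated(stripped)) {
        rownames(m) <- stripped
        assign(nm, m)
      }
    }
  }
  bulk_cpm <- cpm_normalize(bulk)
  pseudo_cpm <- cpm_normalize(sc_pseudobulks)
  n_universe <- length(intersect(rownames(pseudo_cpm), rownames(bulk_cpm)))
  prevalent <- prevalence_filter(bulk_cpm, pseudo_cpm, cpm_threshold, fraction)
  if (!length(prevalent)) {
    abort(sprintf("no gene passed the prevalence filter (shared universe: %d genes)",
                  n_universe))
  }
  d <- vapply(prevalent, function(g) {
    ks_statistic(bulk_cpm[g, ], pseudo_cpm[g, ])
  }, numeric(1))
  retained <- prevalent[d <= ks_threshold]
  if (!length(retained)) {
    abort(sprintf(paste0("no gene survived selection: %d in shared universe, ",
                         "%d past prevalence filter, 0 past KS screen"),
                  n_universe, length(prevalent)))
  }
  stages <- tibble(
    stage = c("shared_universe", "post_prevalence", "post_ks"),
    n_genes = c(n_universe, length(prevalent), length(retained))
  )
  if (verbose) {
    inform(sprintf("feature selection: %d shared -> %d prevalent -> %d retained (D <= %g)",
                   n_universe, length(prevalent), length(retained), ks_threshold))
  }
  fs <- feature_set(retained, provenance = list(
    cpm_threshold = cpm_threshold,
    prevalence_fraction = fraction,
    ks_threshold = ks_threshold,
    n_bulk_samples = ncol(bulk),
    n_pseudobulk_samples = ncol(sc_pseudobulks)
  ))
  structure(list(
    feature_set = fs,
    ks_report = tibble(gene_id = prevalent, D = unname(d),
                       retained = prevalent %in% retained),
    stages = stages
  ), class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  s <- x$stages
  cat(sprintf("<feature_selection> %d shared -> %d prevalent -> %d retained\n",
              s$n_genes[1], s$n_genes[2], s$n_genes[3]))
  invisible(x)
}

#' Serialize / restore a feature set
#'
#' JSON artifact embedding the ordered gene list and the provenance block.
#'
#' @param features a [feature_set()].
#' @param path file path.
#' @export
write_feature_set <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  jsonlite::write_json(
    list(version = "bulkpurity_featureset/1",
         gene_ids = features$gene_ids,
         provenance = features$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(sprintf("cannot read feature set: %s",
                                                    conditionMessage(e))))
  if (!identical(obj$version, "bulkpurity_featureset/1")) {
    abort(sprintf("unsupported feature set version: %s", obj$version %||% "<missing>"))
  }
  feature_set(obj$gene_ids, provenance = as.list(obj$provenance))
}
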