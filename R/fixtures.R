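# Fully synthetic data generator: a labeled multi-sample single-cell corpus
# with distinct malignant / nonmalignant expression programs, lognormal
# inter-patient effects, library-size variation and negative-binomial counts,
# plus a paired bulk-like cohort built from held-out synthetic patients.
# Everything every pipeline stage needs can be generated in memory, so no
# external download is ever required.

#' Synthetic-corpus configuration
#'
#' Defaults describe a small corpus (200 genes, 8 samples, ~300 cells per
#' sample) that exercises the whole pipeline in seconds while keeping the
#' biological structure the method relies on: marker genes separating the
#' two programs (fold change 4), inter-patient expression heterogeneity
#' (lognormal sd 0.15 per gene), per-cell library-size variation and
#' negative-binomial overdispersion.
#'
#' @param n_samples number of synthetic patients in the corpus.
#' @param cells_per_sample inclusive range of cells per sample.
#' @param n_genes gene universe size.
#' @param n_malignant_markers,n_nonmalignant_markers marker genes specific to
#'   each program.
#' @param marker_fold_change multiplicative up-regulation of a program's own
#'   markers (its opposite markers are down-regulated by the same factor).
#' @param patient_effect_sd sd of the per-patient lognormal gene effect
#'   (log scale).
#' @param library_size inclusive range of per-cell total-count rates.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param malignant_fraction range of per-sample malignant fractions.
#' @param gene_length_range range of synthetic gene lengths in bases.
#' @param program_seed seed fixing the gene programs (base rates, marker
#'   assignment) so corpora and bulk cohorts generated from the same
#'   configuration share one synthetic biology.
#' @export
fixture_config <- function(n_samples = 8, cells_per_sample = c(250, 350),
                           n_genes = 200, n_malignant_markers = 30,
                           n_nonmalignant_markers = 30,
                           marker_fold_change = 4, patient_effect_sd = 0.15,
                           library_size = c(1000, 2500), dispersion = 2,
                           malignant_fraction = c(0.15, 0.9),
                           gene_length_range = c(500, 5000),
                           program_seed = 20240901) {
  stopifnot(n_samples >= 1, all(cells_per_sample >= 1),
            length(cells_per_sample) == 2, cells_per_sample[1] <= cells_per_sample[2],
            n_genes >= n_malignant_markers + n_nonmalignant_markers,
            marker_fold_change > 1, patient_effect_sd >= 0,
            all(library_size > 0), dispersion > 0,
            all(malignant_fraction >= 0), all(malignant_fraction <= 1),
            malignant_fraction[1] <= malignant_fraction[2],
            all(gene_length_range > 0))
  structure(list(n_samples = as.integer(n_samples),
                 cells_per_sample = as.integer(cells_per_sample),
                 n_genes = as.integer(n_genes),
                 n_malignant_markers = as.integer(n_malignant_markers),
                 n_nonmalignant_markers = as.integer(n_nonmalignant_markers),
                 marker_fold_change = marker_fold_change,
                 patient_effect_sd = patient_effect_sd,
                 library_size = library_size,
                 dispersion = dispersion,
                 malignant_fraction = malignant_fraction,
                 gene_length_range = gene_length_range,
                 program_seed = as.integer(program_seed)),
            class = "fixture_config")
}

# Gene programs are a pure function of the configuration: base expression
# rates and marker assignment are drawn under program_seed with the ambient
# RNG state preserved, so a corpus and a bulk cohort from the same config
# share the same synthetic genes.
gene_programs <- function(cfg) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$program_seed)
  g <- cfg$n_genes
  gene_ids <- sprintf("g%04d", seq_len(g))
  base <- rlnorm(g, meanlog = 0, sdlog = 1)
  mal_markers <- gene_ids[seq_len(cfg$n_malignant_markers)]
  non_markers <- gene_ids[cfg$n_malignant_markers + seq_len(cfg$n_nonmalignant_markers)]
  fc <- cfg$marker_fold_change
  rate_mal <- base
  rate_mal[gene_ids %in% mal_markers] <- rate_mal[gene_ids %in% mal_markers] * fc
  rate_mal[gene_ids %in% non_markers] <- rate_mal[gene_ids %in% non_markers] / fc
  rate_non <- base
  rate_non[gene_ids %in% non_markers] <- rate_non[gene_ids %in% non_markers] * fc
  rate_non[gene_ids %in% mal_markers] <- rate_non[gene_ids %in% mal_markers] / fc
  lengths <- round(runif(g, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  list(gene_ids = gene_ids,
       rate_malignant = rate_mal / sum(rate_mal),
       rate_nonmalignant = rate_non / sum(rate_non),
       malignant_markers = mal_markers,
       nonmalignant_markers = non_markers,
       lengths = setNames(lengths, gene_ids))
}

#' Synthetic gene lengths
#'
#' The length table paired with a configuration's gene universe. With
#' `uniform = TRUE` all lengths are equal, which makes TPM coincide with CPM
#' — handy for cross-checks.
#'
#' @param cfg a [fixture_config()].
#' @param uniform use one common length for every gene.
#' @return named numeric vector of lengths in bases.
#' @export
generate_gene_lengths <- function(cfg, uniform = FALSE) {
  prog <- gene_programs(cfg)
  if (uniform) setNames(rep(1000, length(prog$lengths)), names(prog$lengths))
  else prog$lengths
}

draw_sample_cells <- function(cfg, prog, sample_id, n_cells, mal_frac, patient_effect) {
  labels <- ifelse(rbinom(n_cells, 1, mal_frac) == 1, "malignant", "nonmalignant")
  libs <- runif(n_cells, cfg$library_size[1], cfg$library_size[2])
  rates <- cbind(malignant = prog$rate_malignant * patient_effect,
                 nonmalignant = prog$rate_nonmalignant * patient_effect)
  rates <- sweep(rates, 2, colSums(rates), "/")
  mu <- rates[, labels, drop = FALSE] * rep(libs, each = cfg$n_genes)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(prog$gene_ids,
                                   sprintf("%s_c%04d", sample_id, seq_len(n_cells))))
  list(counts = counts, labels = labels)
}

#' Generate a labeled synthetic single-cell corpus
#'
#' Per sample: a lognormal per-gene patient effect, a malignant fraction
#' drawn from the configured range, per-cell labels by that fraction, and
#' negative-binomial counts with mean `library_size * program_rate *
#' patient_effect`.
#'
#' @param cfg a [fixture_config()].
#' @param seed optional integer seed for the cell-level randomness (the gene
#'   programs are fixed by `cfg$program_seed` independently).
#' @param sample_prefix prefix for generated sample ids.
#' @return a [single_cell_corpus()]; the per-sample configured and realized
#'   malignant fractions are attached as attribute `truth`, the marker
#'   assignment as attribute `programs`.
#' @export
generate_corpus <- function(cfg = fixture_config(), seed = NULL, sample_prefix = "S") {
  if (!is.null(seed)) set.seed(seed)
  prog <- gene_programs(cfg)
  sample_ids <- sprintf("%s%02d", sample_prefix, seq_len(cfg$n_samples))
  all_counts <- vector("list", cfg$n_samples)
  all_cells <- vector("list", cfg$n_samples)
  truth <- vector("list", cfg$n_samples)
  for (i in seq_len(cfg$n_samples)) {
    pe <- rlnorm(cfg$n_genes, 0, cfg$patient_effect_sd)
    n_cells <- sample(cfg$cells_per_sample[1]:cfg$cells_per_sample[2], 1)
    frac <- runif(1, cfg$malignant_fraction[1], cfg$malignant_fraction[2])
    drawn <- draw_sample_cells(cfg, prog, sample_ids[i], n_cells, frac, pe)
    all_counts[[i]] <- drawn$counts
    all_cells[[i]] <- tibble(cell_id = colnames(drawn$counts),
                             sample_id = sample_ids[i],
                             label = drawn$labels)
    truth[[i]] <- tibble(sample_id = sample_ids[i],
                         configured_fraction = frac,
                         realized_fraction = mean(drawn$labels == "malignant"),
                         n_cells = n_cells)
  }
  corpus <- single_cell_corpus(do.call(cbind, all_counts),
                               dplyr::bind_rows(all_cells))
  attr(corpus, "truth") <- dplyr::bind_rows(truth)
  attr(corpus, "programs") <- prog[c("malignant_markers", "nonmalignant_markers")]
  corpus
}

#' Generate a paired bulk-like cohort from held-out synthetic patients
#'
#' Each bulk column mixes freshly drawn malignant and nonmalignant cells from
#' one held-out synthetic patient (new patient effects, same gene programs as
#' the corpus configuration) at a drawn purity, then resamples the summed
#' profile with Poisson noise — a bulk-sequencing surrogate sharing the
#' corpus biology without sharing any cells.
#'
#' @param cfg a [fixture_config()].
#' @param n_bulk number of bulk samples (must be positive).
#' @param n_patients held-out synthetic patients backing the cohort.
#' @param purity_range purity draw range; defaults to the configured
#'   malignant-fraction range so the cohorts match compositionally.
#' @param cells_per_bulk cells mixed into each bulk profile.
#' @param seed optional integer seed.
#' @return list with `counts` (genes x n_bulk matrix) and `truth` tibble
#'   (`sample_id`, `purity`, `patient`).
#' @export
generate_bulk_cohort <- function(cfg = fixture_config(), n_bulk = 50,
                                 n_patients = 4, purity_range = NULL,
                                 cells_per_bulk = 1000, seed = NULL) {
  if (n_bulk < 1) abort("n_bulk must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  purity_range <- purity_range %||% cfg$malignant_fraction
  prog <- gene_programs(cfg)
  effects <- replicate(n_patients, rlnorm(cfg$n_genes, 0, cfg$patient_effect_sd),
                       simplify = FALSE)
  counts <- matrix(0, nrow = cfg$n_genes, ncol = n_bulk,
                   dimnames = list(prog$gene_ids, sprintf("bulk%03d", seq_len(n_bulk))))
  truth <- tibble(sample_id = colnames(counts),
                  purity = runif(n_bulk, purity_range[1], purity_range[2]),
                  patient = sample.int(n_patients, n_bulk, replace = TRUE))
  for (j in seq_len(n_bulk)) {
    pe <- effects[[truth$patient[j]]]
    n_mal <- as.integer(round_half_away(truth$purity[j] * cells_per_bulk))
    n_non <- cells_per_bulk - n_mal
    profile <- numeric(cfg$n_genes)
    if (n_mal > 0) {
      d <- draw_sample_cells(cfg, prog, "tmp", n_mal, 1, pe)
      profile <- profile + rowSums(d$counts)
    }
    if (n_non > 0) {
      d <- draw_sample_cells(cfg, prog, "tmp", n_non, 0, pe)
      profile <- profile + rowSums(d$counts)
    }
    counts[, j] <- rpois(cfg$n_genes, profile)
  }
  list(counts = counts, truth = truth)
}

#' Multiply a random gene subset by a shift factor
#'
#' Injects a cross-modality inconsistency into a bulk matrix: a random
#' fraction of genes has its counts multiplied by `shift_factor`, and the
#' affected gene ids are returned so the KS screen's sensitivity can be
#' measured.
#'
#' @param bulk genes x samples count matrix.
#' @param shifted_gene_fraction fraction of genes to shift (0–1).
#' @param shift_factor multiplicative factor (1 = identity).
#' @param seed optional integer seed for the subset draw.
#' @return list with `counts` (shifted matrix) and `shifted_genes`.
#' @export
inject_modality_shift <- function(bulk, shifted_gene_fraction = 0.1,
                                  shift_factor = 20, seed = NULL) {
  stopifnot(shifted_gene_fraction >= 0, shifted_gene_fraction <= 1,
            shift_factor > 0)
  bulk <- as_count_matrix(bulk)
  if (!is.null(seed)) set.seed(seed)
  n_shift <- floor(shifted_gene_fraction * nrow(bulk))
  shifted <- if (n_shift > 0) sort(sample(rownames(bulk), n_shift)) else character(0)
  bulk[shifted, ] <- bulk[shifted, , drop = FALSE] * shift_factor
  list(counts = bulk, shifted_genes = shifted)
}
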