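test_that("KS statistic matches forced cases and is symmetric", {
  expect_equal(ks_statistic(c(1, 2, 2, 3), c(3, 2, 1, 2)), 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)),
               ks_statistic(c(2, 3, 4), c(1, 2, 3)))
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("KS agrees with ECDF enumeration and ks.test on random data", {
  set.seed(41)
  for (i in 1:50) {
    a <- sample(0:8, sample(3:30, 1), replace = TRUE)  # heavy ties
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    expect_equal(ks_statistic(a, b), oracle_ks(a, b), tolerance = 1e-14)
    d_ref <- suppressWarnings(stats::ks.test(a, b)$statistic)
    expect_equal(ks_statistic(a, b), unname(d_ref), tolerance = 1e-12)
  }
})

test_that("prevalence filter excludes at the 50% boundary in either modality", {
  # 8 bulk samples; gene rows engineered in CPM space directly
  bulk <- rbind(
    low_half   = c(0.5, 0.5, 0.5, 0.5, 2, 2, 2, 2),  # exactly half below 1 -> out
    low_three  = c(0.5, 0.5, 0.5, 2, 2, 2, 2, 2),    # 3/8 below -> stays
    all_high   = rep(5, 8),
    all_zero   = rep(0, 8)
  )
  colnames(bulk) <- paste0("b", 1:8)
  pseudo <- matrix(5, nrow(bulk), 4,
                   dimnames = list(rownames(bulk), paste0("p", 1:4)))
  pseudo["all_zero", ] <- 0
  kept <- prevalence_filter(bulk, pseudo)
  expect_setequal(kept, c("low_three", "all_high"))

  # exclusion driven by the pseudobulk side alone
  pseudo["all_high", 1:2] <- 0
  expect_setequal(prevalence_filter(bulk, pseudo), "low_three")

  expect_error(prevalence_filter(bulk, matrix(1, 1, 1, dimnames = list("other", "p1"))),
               "no genes shared")
})

test_that("select_features screens divergent genes and keeps consistent ones", {
  set.seed(42)
  n <- 12
  genes <- sprintf("g%02d", 1:n)
  base <- matrix(rpois(n * 20, 40) + 10, n, 20, dimnames = list(genes, paste0("b", 1:20)))
  pseudo <- matrix(rpois(n * 20, 40) + 10, n, 20, dimnames = list(genes, paste0("p", 1:20)))
  # one gene expressed in bulk only (absent from every pseudobulk sample)
  bulk <- base
  pseudo["g01", ] <- 0
  sel <- select_features(bulk, pseudo)
  expect_false("g01" %in% sel$feature_set$gene_ids)

  # identical per-gene distributions in both modalities: everything retained
  same <- base
  colnames(same) <- paste0("p", 1:20)
  sel2 <- select_features(base, same)
  expect_identical(sel2$feature_set$gene_ids, genes)
  expect_true(all(tidy(sel2)$D == 0))
})

test_that("selection is invariant to column order and monotone in the threshold", {
  set.seed(43)
  bulk <- random_counts(15, 12, max_count = 80) + 5
  pseudo <- random_counts(15, 9, max_count = 80) + 5
  colnames(pseudo) <- paste0("p", 1:9)
  sel <- select_features(bulk, pseudo, ks_threshold = 0.5)
  shuf <- select_features(bulk[, sample(ncol(bulk))], pseudo[, sample(ncol(pseudo))],
                          ks_threshold = 0.5)
  expect_identical(sel$feature_set$gene_ids, shuf$feature_set$gene_ids)

  for (th in c(0.2, 0.4, 0.6)) {
    lo <- tryCatch(select_features(bulk, pseudo, ks_threshold = th)$feature_set$gene_ids,
                   error = function(e) character(0))
    hi <- select_features(bulk, pseudo, ks_threshold = th + 0.2)$feature_set$gene_ids
    expect_true(all(lo %in% hi))
  }
})

test_that("selection equals an independently coded two-pass filter", {
  set.seed(44)
  bulk <- random_counts(25, 14, max_count = 60)
  pseudo <- random_counts(25, 10, max_count = 60)
  bulk[1, ] <- bulk[1, ] + 1
  pseudo[1, ] <- pseudo[1, ] + 1
  colnames(pseudo) <- paste0("p", 1:10)

  # oracle: plain loops from the definitions
  bc <- oracle_cpm(bulk)
  pc <- oracle_cpm(pseudo)
  keep <- character(0)
  for (g in rownames(pseudo)) {
    if (mean(bc[g, ] < 1) >= 0.5 || mean(pc[g, ] < 1) >= 0.5) next
    if (oracle_ks(bc[g, ], pc[g, ]) > 0.4) next
    keep <- c(keep, g)
  }
  sel <- select_features(bulk, pseudo)
  expect_identical(sel$feature_set$gene_ids, keep)
  expect_identical(glance(sel)$post_ks, length(keep))
})

test_that("feature sets serialize with provenance and validate on load", {
  fs <- feature_set(c("a", "b", "c"),
                    provenance = list(cpm_threshold = 1, ks_threshold = 0.4))
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_set(fs, path)
  back <- read_feature_set(path)
  expect_identical(back$gene_ids, fs$gene_ids)
  expect_equal(back$provenance$ks_threshold, 0.4)

  writeLines('{"version": "bogus/9", "gene_ids": ["a"]}', path)
  expect_error(read_feature_set(path), "version")
  expect_error(feature_set(character(0)), "empty")
  expect_error(feature_set(c("a", "a")), "unique")
})
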