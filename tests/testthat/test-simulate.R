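toy <- local({
  set.seed(61)
  spec <- list(
    A = list(mal = matrix(rpois(36, 8), 3), non = matrix(rpois(30, 4), 3)),
    B = list(mal = matrix(rpois(18, 8), 3), non = matrix(rpois(21, 4), 3))
  )
  make_corpus(spec, c("g1", "g2", "g3"))
})

test_that("purity boundaries and rounding behave as specified", {
  set.seed(62)
  pb0 <- simulate_pseudobulk(toy, "A", p = 0, N = 40)
  expect_equal(pb0$purity, 0)
  expect_equal(pb0$n_malignant, 0L)

  pb5 <- simulate_pseudobulk(toy, "A", p = 0.5, N = 200)
  expect_equal(pb5$n_malignant, 100L)
  expect_equal(pb5$purity, 0.5)

  # round half away from zero: p*N = 2.5 -> Nm = 3
  pb <- simulate_pseudobulk(toy, "A", p = 0.25, N = 10)
  expect_equal(pb$n_malignant, 3L)
  expect_equal(pb$purity, 0.3)
})

test_that("labels are exactly Nm/N and within 0.5/N of the target", {
  set.seed(63)
  for (i in 1:40) {
    p <- runif(1)
    N <- sample(5:300, 1)
    pb <- simulate_pseudobulk(toy, sample(c("A", "B"), 1), p, N,
                              min_cells_per_class = 5)
    expect_identical(pb$purity, pb$n_malignant / N)
    expect_lte(abs(pb$purity - p), 0.5 / N + 1e-12)
    expect_true(all(pb$counts >= 0))
  }
})

test_that("a seeded draw replays the documented RNG order exactly", {
  ids <- toy$cells$cell_id[toy$cells$sample_id == "A"]
  mal <- toy$counts[, intersect(ids, toy$cells$cell_id[toy$cells$label == "malignant"]), drop = FALSE]
  non <- toy$counts[, intersect(ids, toy$cells$cell_id[toy$cells$label == "nonmalignant"]), drop = FALSE]

  set.seed(777)
  pb <- simulate_pseudobulk(toy, "A", p = 0.3, N = 10)

  set.seed(777)
  Nm <- 3L  # round(0.3 * 10)
  mi <- sample.int(ncol(mal), Nm, replace = TRUE)
  ni <- sample.int(ncol(non), 10L - Nm, replace = TRUE)
  manual <- rowSums(mal[, mi, drop = FALSE]) + rowSums(non[, ni, drop = FALSE])
  expect_equal(unname(pb$counts), unname(manual))
})

test_that("simulation never crosses samples (private-marker corpus)", {
  corpus <- private_marker_corpus(n_samples = 3)
  set.seed(64)
  for (s in c("P1", "P2", "P3")) {
    pb <- simulate_pseudobulk(corpus, s, p = 0.5, N = 30, min_cells_per_class = 5)
    own <- paste0("marker_", sub("P", "", s))
    foreign <- setdiff(sprintf("marker_%d", 1:3), own)
    expect_gt(pb$counts[own], 0)
    expect_true(all(pb$counts[foreign] == 0))
  }
  expect_error(simulate_pseudobulk(corpus, "P1", 0.5, 10, min_cells_per_class = 10),
               "eligible")
})

test_that("expected mixture counts follow the analytic mean", {
  corpus <- private_marker_corpus(n_samples = 1, cells_per_class = 8)
  ids <- corpus$cells
  mal_mean <- rowMeans(corpus$counts[, ids$cell_id[ids$label == "malignant"]])
  non_mean <- rowMeans(corpus$counts[, ids$cell_id[ids$label == "nonmalignant"]])
  p <- 0.25; N <- 80; reps <- 300
  set.seed(65)
  acc <- matrix(0, nrow(corpus$counts), reps)
  for (r in seq_len(reps)) {
    acc[, r] <- simulate_pseudobulk(corpus, "P1", p, N)$counts
  }
  expected <- N * (p * mal_mean + (1 - p) * non_mean)
  mc_se <- apply(acc, 1, stats::sd) / sqrt(reps)
  expect_true(all(abs(rowMeans(acc) - expected) <= 4 * mc_se + 1e-9))
})

test_that("batches have the right shape, labels and determinism", {
  lens <- setNames(rep(1000, 3), c("g1", "g2", "g3"))
  cfg <- simulation_config(cells_min = 10, cells_max = 50, batch_size = 16,
                           min_cells_per_class = 5)
  set.seed(66)
  b <- simulate_batch(toy, c("g1", "g2", "g3"), lens, cfg)
  expect_identical(dim(b$x), c(16L, 3L))
  expect_length(b$purity, 16)
  expect_true(all(b$sample_id %in% c("A", "B")))

  pure <- simulation_config(purity_min = 1, purity_max = 1, cells_min = 10,
                            cells_max = 20, batch_size = 8, min_cells_per_class = 5)
  set.seed(67)
  expect_true(all(simulate_batch(toy, c("g1", "g2", "g3"), lens, pure)$purity == 1))

  set.seed(68); b1 <- simulate_batch(toy, c("g1", "g2", "g3"), lens, cfg)
  set.seed(68); b2 <- simulate_batch(toy, c("g1", "g2", "g3"), lens, cfg)
  expect_identical(b1, b2)
})

test_that("simulated purity labels are uniform on average", {
  lens <- setNames(rep(1000, 3), c("g1", "g2", "g3"))
  cfg <- simulation_config(cells_min = 5, cells_max = 20, batch_size = 64,
                           min_cells_per_class = 5)
  set.seed(69)
  labels <- unlist(lapply(1:40, function(i) {
    simulate_batch(toy, c("g1", "g2", "g3"), lens, cfg)$purity
  }))
  # mean of U(0,1) labels: 0.5 within 3 standard errors
  se <- stats::sd(labels) / sqrt(length(labels))
  expect_lt(abs(mean(labels) - 0.5), 3 * se + 0.02)
})
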