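# A tiny trained model shared across the blocks below: 30 genes, 3 samples,
# short schedule (small window/patience) — enough to exercise the training
# contract without the full experiment (which lives in the acceptance tests).
tiny <- local({
  cfg <- fixture_config(n_samples = 3, cells_per_sample = c(60, 80), n_genes = 30,
                        n_malignant_markers = 6, n_nonmalignant_markers = 6,
                        program_seed = 7)
  corpus <- generate_corpus(cfg, seed = 71)
  lengths <- generate_gene_lengths(cfg)
  features <- feature_set(rownames(corpus$counts))
  sim <- simulation_config(cells_min = 20, cells_max = 60)
  mcfg <- model_config(window = 5, patience = 10, max_batches = 120)
  fit <- train_purity_model(corpus, features, lengths, sim, mcfg, seed = 72)
  list(cfg = cfg, corpus = corpus, lengths = lengths, features = features,
       sim = sim, mcfg = mcfg, fit = fit)
})

test_that("l1 loss is the mean absolute deviation", {
  expect_equal(l1_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(l1_loss(c(0, 1), c(1, 0)), 1)
  expect_equal(l1_loss(c(0.2, 0.8), c(0.3, 0.7)), 0.1)
  expect_error(l1_loss(1:3, 1:2), "length mismatch")
})

test_that("architecture, parameter count and seeded initialisation", {
  feats <- sprintf("g%d", 1:5)
  m <- init_purity_model(feats, model_config(), seed = 3)
  expect_equal(n_parameters(m), 5 * 32 + 32 + 32 * 16 + 16 + 16 + 1)
  expect_identical(vapply(m$layers, function(l) dim(l$W)[2], numeric(1)),
                   c(32, 16, 1))
  m2 <- init_purity_model(feats, model_config(), seed = 3)
  expect_identical(m$layers, m2$layers)

  # zeroed weights: eval-mode forward of anything is the zero bias
  m$layers <- lapply(m$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  counts <- matrix(1:5, 5, 1, dimnames = list(feats, "s1"))
  pred <- predict(m, counts, setNames(rep(1000, 5), feats))
  expect_equal(pred$raw_output, 0)
})

test_that("training tracks the sliding window and returns the best snapshot", {
  log <- tiny$fit$training_log
  tr <- tiny$fit$training
  expect_s3_class(log, "purity_training_log")
  expect_true(all(is.na(log$window_mean[seq_len(tiny$mcfg$window - 1)])))
  wm <- log$window_mean[!is.na(log$window_mean)]
  expect_equal(tr$best_window_mean, min(wm))
  expect_equal(log$window_mean[tr$best_batch], min(wm))
  expect_true(tr$stop_reason %in% c("patience", "max_batches"))
  if (tr$stop_reason == "patience") {
    expect_equal(tr$n_batches - tr$best_batch, tiny$mcfg$patience)
  }
  # manual sliding mean recomputation
  w <- tiny$mcfg$window
  manual <- vapply(w:nrow(log), function(b) mean(log$loss[(b - w + 1):b]), numeric(1))
  expect_equal(wm, manual)
})

test_that("training is deterministic: same seed gives byte-identical artifacts", {
  fit2 <- train_purity_model(tiny$corpus, tiny$features, tiny$lengths,
                             tiny$sim, tiny$mcfg, seed = 72)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_purity_model(tiny$fit, f1)
  save_purity_model(fit2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("predictions are clipped, deterministic and bounded for any input", {
  set.seed(73)
  counts <- matrix(rpois(30 * 6, 40), 30, 6,
                   dimnames = list(rownames(tiny$corpus$counts), paste0("s", 1:6)))
  p1 <- predict(tiny$fit, counts, tiny$lengths)
  p2 <- predict(tiny$fit, counts, tiny$lengths)
  expect_identical(p1, p2)
  expect_true(all(p1$purity >= 0 & p1$purity <= 1))
  expect_equal(p1$purity, pmin(pmax(p1$raw_output, 0), 1))

  # force a raw output above 1 via the output bias; it reports exactly 1
  inflated <- tiny$fit
  inflated$layers[[3]]$b <- inflated$layers[[3]]$b + 10
  expect_equal(predict(inflated, counts, tiny$lengths)$purity, rep(1, 6))
  expect_gt(max(predict(inflated, counts, tiny$lengths)$raw_output), 1)
})

test_that("missing-gene guards warn above 1% and refuse at 20%", {
  feats <- sprintf("g%03d", 1:100)
  model <- init_purity_model(feats, model_config(), seed = 74)
  lens <- setNames(rep(1000, 100), feats)
  full <- matrix(rpois(100 * 2, 30) + 1, 100, 2,
                 dimnames = list(feats, c("s1", "s2")))

  expect_silent(predict(model, full, lens))
  two_missing <- full[-(1:2), ]  # 2% missing: warn, still predicts
  expect_warning(pred <- predict(model, two_missing, lens), "missing")
  expect_equal(unique(pred$missing_fraction), 0.02)
  expect_identical(unique(pred$flag), "missing_genes")

  expect_error(predict(model, full[-(1:25), ], lens), "refusing")   # 25%
  expect_error(predict(model, full[-(1:20), ], lens), "refusing")   # exactly 20%
  expect_warning(predict(model, full[-(1:19), ], lens), "missing")  # 19% warns
})

test_that("model artifacts round-trip exactly and validate their schema", {
  path <- withr::local_tempfile(fileext = ".json")
  save_purity_model(tiny$fit, path)
  back <- load_purity_model(path)
  expect_identical(back$feature_ids, tiny$fit$feature_ids)
  expect_identical(back$layers, tiny$fit$layers)

  set.seed(75)
  counts <- matrix(rpois(30 * 3, 50), 30, 3,
                   dimnames = list(rownames(tiny$corpus$counts), paste0("s", 1:3)))
  expect_identical(predict(back, counts, tiny$lengths),
                   predict(tiny$fit, counts, tiny$lengths))

  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 100), path)
  expect_error(load_purity_model(path), "cannot read")

  jsonlite::write_json(list(version = "bulkpurity_model/1"), path, auto_unbox = TRUE)
  expect_error(load_purity_model(path), "feature set")
  jsonlite::write_json(list(version = "other/2"), path, auto_unbox = TRUE)
  expect_error(load_purity_model(path), "version")
})

test_that("held-out error shrinks as marker signal strengthens", {
  maes <- vapply(c(1.5, 4, 12), function(fc) {
    cfg <- fixture_config(n_samples = 3, cells_per_sample = c(60, 80), n_genes = 30,
                          n_malignant_markers = 6, n_nonmalignant_markers = 6,
                          marker_fold_change = fc, program_seed = 7)
    corpus <- generate_corpus(cfg, seed = 76)
    lengths <- generate_gene_lengths(cfg)
    fit <- train_purity_model(corpus, feature_set(rownames(corpus$counts)), lengths,
                              simulation_config(cells_min = 20, cells_max = 60),
                              model_config(max_batches = 4000), seed = 77)
    hold <- generate_corpus(cfg, seed = 78, sample_prefix = "H")
    set.seed(79)
    elig <- eligible_samples(hold)
    sims <- lapply(1:60, function(i) {
      simulate_pseudobulk(hold, sample(elig, 1), runif(1), sample(50:150, 1))
    })
    counts <- vapply(sims, `[[`, numeric(30), "counts")
    colnames(counts) <- paste0("e", 1:60)
    ev <- evaluate_purity(fit, counts,
                          setNames(vapply(sims, `[[`, numeric(1), "purity"),
                                   colnames(counts)), lengths)
    ev$metrics$mae
  }, numeric(1))
  expect_identical(order(maes, decreasing = TRUE), 1:3)
})
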