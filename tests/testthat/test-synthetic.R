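test_that("the generator is deterministic, byte for byte", {
  cfg <- synth_config(n_targets = 10, n_compounds = 40, seed = 23,
                      mean_ligands = 8)
  b1 <- generate_benchmark(cfg)
  b2 <- generate_benchmark(cfg)
  expect_identical(b1$compounds$smiles, b2$compounds$smiles)
  expect_identical(b1$activities, b2$activities)
  expect_identical(b1$panel$sequences, b2$panel$sequences)
  d1 <- tempfile(); d2 <- tempfile()
  write_benchmark(b1, d1); write_benchmark(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("every grammar assembly parses to a valid molecule", {
  b <- fx_bench()
  expect_equal(b$compounds$n_rejected, 0)
  expect_true(all(vapply(b$compounds$mols, function(m) m$n_heavy >= 1,
                         logical(1))))
})

test_that("the activity table exercises both labels and the small-target rule", {
  b <- fx_bench()
  rec <- fx_records()
  cnt <- table(rec$target_id)
  big <- names(cnt)[cnt > 5]
  frac_both <- mean(vapply(big, function(t) {
    lab <- rec$label[rec$target_id == t]
    length(unique(lab)) == 2
  }, logical(1)))
  expect_gte(frac_both, 0.9)
  expect_gte(sum(cnt <= 5), 1)      # small targets exist
  expect_true(all(b$activities$ki_nM > 0))
})

test_that("truth pairs are a subset of the activity table", {
  b <- fx_bench()
  tt <- truth_table(b)
  akey <- paste(b$activities$compound_id, b$activities$target_id)
  expect_true(all(paste(tt$compound_id, tt$target_id) %in% akey))
  # non-small targets have at least one planted positive
  cnt <- table(b$activities$target_id)
  big <- names(cnt)[cnt > 5]
  expect_true(all(big %in% tt$target_id))
})

test_that("noise-free truth matches thresholded labels", {
  cfg <- synth_config(n_targets = 10, n_compounds = 60, seed = 3,
                      mean_ligands = 10, noise_sd = 0)
  b <- generate_benchmark(cfg)
  rec <- suppressMessages(label_interactions(aggregate_bioactivities(b$activities)))
  tkey <- paste(b$truth$compound_id, b$truth$target_id)
  rkey <- paste(rec$compound_id, rec$target_id)
  expect_equal(sort(rkey[rec$label == 1]), sort(intersect(tkey, rkey)))
})

test_that("held-out performance tracks the planted signal strength", {
  # ECFP4-ProA member, pooled 4-fold out-of-fold AUC, on the cached
  # benchmark (beta = 1.5) versus a no-signal twin (beta = 0)
  oof_auc <- function(f, seed) {
    fold <- targetfisher:::tf_stratified_folds(f$y, 4, seed)
    oof <- rep(NA_real_, length(f$y))
    for (k in 1:4) {
      te <- fold == k
      m <- grid_search_train(f$x[!te, , drop = FALSE], f$y[!te],
                             fast_grid(), seed = 17, scheme = "sig")
      oof[te] <- predict_scheme(m, f$x[te, , drop = FALSE])
    }
    roc_auc(f$y, oof)
  }
  auc_signal <- oof_auc(fx_features()$features[["ECFP4-ProA"]], 99)

  b0 <- generate_benchmark(synth_config(n_targets = 12, n_compounds = 80,
                                        seed = 11, mean_ligands = 14,
                                        beta = 0))
  rec0 <- suppressMessages(label_interactions(aggregate_bioactivities(b0$activities)))
  f0 <- build_pair_features(rec0, featurize_compounds(b0$compounds, "ECFP4"),
                            compute_proa_panel(b0$panel), "ECFP4-ProA")
  auc_null <- oof_auc(f0, 99)
  expect_gt(auc_signal, auc_null)
  expect_gt(auc_signal, 0.55)
  expect_lt(auc_null, 0.62)
})
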