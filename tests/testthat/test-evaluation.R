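fx_toy_records <- function(n_targets = 20, n_compounds = 120, seed = 8,
                           per_target = 50) {
  set.seed(seed)
  rec <- do.call(rbind, lapply(seq_len(n_targets), function(t) {
    n <- if (t <= 2) 3 else per_target     # two small targets
    data.frame(compound_id = sample(sprintf("c%03d", seq_len(n_compounds)), n),
               target_id = sprintf("t%02d", t),
               label = rbinom(n, 1, 0.5), stringsAsFactors = FALSE)
  }))
  rec
}

test_that("pair-split folds force small targets into training and spread the rest", {
  rec <- fx_toy_records()
  f <- make_folds(rec, "pair", 10, seed = 4)
  small <- rec$target_id %in% c("t01", "t02")
  expect_true(all(f$fold[small] == 0))
  expect_true(all(f$fold[!small] %in% 1:10))
  for (t in unique(rec$target_id[!small])) {
    expect_gte(length(unique(f$fold[rec$target_id == t])), 2)
  }
  # stratification balance: fold sizes within +/-10% of n/10, over 20 seeds
  rec2 <- fx_toy_records(n_targets = 22, per_target = 50)[1:1000, ]
  for (s in 1:20) {
    f2 <- make_folds(rec2, "pair", 10, seed = s)
    sizes <- tabulate(f2$fold[f2$fold > 0], 10)
    expect_true(all(abs(sizes - mean(sizes)) <= 0.1 * mean(sizes) + 1))
  }
})

test_that("compound-split folds never share a compound", {
  rec <- fx_toy_records()
  f <- make_folds(rec, "compound", 10, seed = 4)
  byc <- split(f$fold, rec$compound_id)
  expect_true(all(vapply(byc, function(v) length(unique(v)) == 1, logical(1))))
  expect_error(make_folds(rec[1:5, ], "pair", 10), "fewer records")
})

test_that("classification metrics follow the confusion-matrix formulas", {
  # TP=3, FN=2, TN=2, FP=1
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.2)
  cm <- classification_metrics(labels, scores)
  expect_equal(cm[c("TP", "FN", "TN", "FP")], list(TP = 3L, FN = 2L, TN = 2L, FP = 1L))
  expect_equal(cm$ACC, 5 / 8)
  expect_equal(cm$SE, 3 / 5)
  expect_equal(cm$SP, 2 / 3)
  perfect <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(perfect$ACC, perfect$SE, perfect$SP, perfect$AUC),
               c(1, 1, 1, 1))
  expect_error(classification_metrics(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("AUC equals brute-force pair counting and is rank-invariant", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  set.seed(12)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)   # rounded to force ties
    expect_equal(roc_auc(labels, scores), fx_auc_brute(labels, scores),
                 tolerance = 1e-12)
  }
  labels <- c(1, 1, 0, 0, 1, 0)
  scores <- runif(6)
  expect_equal(roc_auc(labels, scores), roc_auc(labels, scores + 100))
})

test_that("recall@k counts ranked known targets with exact boundaries", {
  rankings <- do.call(rbind, lapply(c("c1", "c2", "c3"), function(cid)
    data.frame(compound_id = cid, target_id = sprintf("t%02d", 1:20),
               rank = 1:20)))
  pos <- data.frame(compound_id = c("c1", "c2", "c3"),
                    target_id = c("t01", "t01", "t11"))
  expect_equal(recall_at_k(rankings, pos[1:2, ], 1), 100)
  expect_equal(recall_at_k(rankings, pos, 10), 100 * 2 / 3)
  expect_equal(recall_at_k(rankings, pos, 11), 100)       # rank 11 enters at k=11
  expect_equal(recall_at_k(rankings, pos, 20), 100)       # full panel
  rec_k <- vapply(1:20, function(k) recall_at_k(rankings, pos, k), numeric(1))
  expect_true(all(diff(rec_k) >= 0))
  # compound-level variant
  pos2 <- data.frame(compound_id = c("c1", "c1"), target_id = c("t01", "t15"))
  expect_equal(recall_at_k(rankings, pos2, 5, level = "pair"), 50)
  expect_equal(recall_at_k(rankings, pos2, 5, level = "compound"), 100)
  expect_error(recall_at_k(rankings, data.frame(compound_id = "cX",
                                                target_id = "t01"), 1),
               "no ranking")
})

test_that("enrichment folds reproduce the bracket arithmetic", {
  expect_equal(enrichment_fold(100 * 5 / 50, 5, 50)$fold, 1)   # random level
  expect_equal(enrichment_fold(50, 10, 60)$fold, 3)
  expect_error(enrichment_fold(10, 0, 60), "k must be")
})

test_that("the cross-validated protocol is deterministic and self-consistent", {
  fx <- fx_features()
  args <- list(fx$records, fx$features, fx$pf, fx$cf, fx$panel_ids,
               mode = "pair", n_folds = 4L, n_repeats = 1L,
               grid = fast_grid(), strategy = "mean", seed = 31)
  r1 <- do.call(run_cv, args)
  r2 <- do.call(run_cv, args)
  expect_equal(r1$classification, r2$classification, tolerance = 1e-12)
  expect_equal(r1$recall, r2$recall, tolerance = 1e-12)
  # sd is zero with one repeat; recall is monotone; full panel = 100%
  expect_true(all(r1$classification["sd", ] == 0))
  expect_true(all(diff(r1$recall["mean", ]) >= -1e-9))
  # aggregate mean equals the single repeat's value when n_repeats = 1
  expect_equal(r1$classification["mean", "ACC"],
               r1$per_repeat$classification[[1]]$ACC)
  # recall at the full panel size is 100%
  rfull <- do.call(run_cv, list(fx$records, fx$features, fx$pf, fx$cf,
                                fx$panel_ids, mode = "pair", n_folds = 4L,
                                n_repeats = 1L, grid = fast_grid(),
                                strategy = "mean", seed = 31,
                                top_k_max = length(fx$panel_ids)))
  expect_equal(unname(rfull$recall["mean", length(fx$panel_ids)]), 100)
})

test_that("the maximum ensemble dominates the mean elementwise in sensitivity", {
  fx <- fx_features()
  rmax <- run_cv(fx$records, fx$features, fx$pf, fx$cf, fx$panel_ids,
                 mode = "pair", n_folds = 4L, n_repeats = 1L,
                 grid = fast_grid(), strategy = "max", seed = 31)
  rmean <- run_cv(fx$records, fx$features, fx$pf, fx$cf, fx$panel_ids,
                  mode = "pair", n_folds = 4L, n_repeats = 1L,
                  grid = fast_grid(), strategy = "mean", seed = 31)
  expect_gte(rmax$per_repeat$classification[[1]]$SE,
             rmean$per_repeat$classification[[1]]$SE)
})
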