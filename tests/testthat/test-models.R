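# Toy training set: two Gaussian blobs, linearly separable.
fx_blobs <- function(n = 200, p = 12, sep = 4, seed = 5) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1, 1:3] <- x[y == 1, 1:3] + sep
  list(x = x, y = y)
}

test_that("a separable toy set is fit perfectly and deterministically", {
  d <- fx_blobs()
  m1 <- grid_search_train(d$x, d$y, fast_grid(), seed = 9, scheme = "toy")
  pred <- predict_scheme(m1, d$x)
  expect_true(all(pred >= 0 & pred <= 1))
  expect_equal(mean((pred >= 0.5) == d$y), 1)   # training ACC 1.0
  m2 <- grid_search_train(d$x, d$y, fast_grid(), seed = 9, scheme = "toy")
  expect_identical(predict_scheme(m2, d$x), pred)
  expect_identical(m1$params, m2$params)
  # contract errors
  expect_error(grid_search_train(d$x, rep(1, nrow(d$x)), fast_grid()),
               "single-class")
  xb <- d$x; xb[3, 4] <- NA
  expect_error(grid_search_train(xb, d$y, fast_grid()), "row 3")
  expect_error(predict_scheme(m1, d$x[, 1:5]), "manifest")
})

test_that("grid search picks the same cell as an external exhaustive loop", {
  d <- fx_blobs(n = 160, p = 8, sep = 1.2, seed = 3)
  grid <- default_grid(eta = c(0.05, 0.4), max_depth = 3, gamma = 0,
                       nrounds = c(10, 40))
  nf <- 5L
  m <- grid_search_train(d$x, d$y, grid, seed = 21, scheme = "gs", nfolds = nf)
  # oracle: independently refit every cell on the same stratified folds
  fold <- targetfisher:::tf_stratified_folds(
    d$y, nf, targetfisher:::tf_subseed(21, "gs", "cvfold"))
  oracle_auc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(nf), function(f) {
      tr <- fold != f
      bst <- targetfisher:::tf_xgb_fit(d$x[tr, ], d$y[tr], grid[g, ],
                                       targetfisher:::tf_subseed(21, "gs", g, f))
      roc_auc(d$y[!tr], predict(bst, targetfisher:::tf_dmatrix(d$x[!tr, ])))
    }, numeric(1)))
  }, numeric(1))
  best <- order(-oracle_auc, grid$nrounds, grid$max_depth)[1]
  expect_equal(as.list(grid[best, ]), m$params[names(grid)])
  expect_equal(oracle_auc, m$grid_auc, tolerance = 1e-12)
})

test_that("ensemble fusion follows its definitions", {
  s <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  one_row <- matrix(s, nrow = 1)
  expect_equal(ensemble_scores(one_row, "mean"), 0.35)
  expect_equal(ensemble_scores(one_row, "max"), 0.6)
  set.seed(4)
  mat <- matrix(runif(600), 100, 6)
  expect_true(all(ensemble_scores(mat, "max") >= ensemble_scores(mat, "mean")))
  expect_equal(ensemble_scores(mat, "mean"), rowMeans(mat), tolerance = 1e-15)
  meta <- c(-1, rep(0.5, 6))
  expect_equal(ensemble_scores(mat, "stacked", meta),
               plogis(-1 + mat %*% rep(0.5, 6))[, 1], tolerance = 1e-12)
  expect_error(ensemble_scores(list(1:3, 1:2, 1:3, 1:3, 1:3, 1:3), "mean"),
               "length")
  expect_error(ensemble_scores(mat, "stacked"), "meta")
})

test_that("the six-member system trains, fuses and serializes consistently", {
  fx <- fx_features()
  ens <- train_full_system(fx$records, fx$features, grid = fast_grid(),
                           strategy = "mean", seed = 13)
  expect_length(ens$members, 6)
  expect_equal(unname(ens$manifest$lengths),
               unname(vapply(fx$features, function(f) ncol(f$x), numeric(1))))
  member_scores <- vapply(names(fx$features), function(s)
    predict_scheme(ens$members[[s]], fx$features[[s]]$x),
    numeric(length(fx$records$label)))
  fused <- ensemble_scores(member_scores, "mean")
  expect_equal(fused, rowMeans(member_scores), tolerance = 1e-12)
  # determinism across retraining
  ens2 <- train_full_system(fx$records, fx$features, grid = fast_grid(),
                            strategy = "mean", seed = 13)
  expect_equal(predict_scheme(ens2$members[[1]], fx$features[[1]]$x),
               member_scores[, 1], tolerance = 1e-15)
  # stacked meta is finite and produces probabilities
  ens_st <- train_full_system(fx$records, fx$features, grid = fast_grid(),
                              strategy = "stacked", seed = 13)
  expect_length(ens_st$meta, 7)
  st <- ensemble_scores(member_scores, "stacked", ens_st$meta)
  expect_true(all(st >= 0 & st <= 1))
})
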