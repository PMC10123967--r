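# Gradient-boosted-tree scheme models and their ensembles.
#
# One binary classifier per descriptor scheme, tuned by exhaustive grid
# search with internal stratified 10-fold CV (selection criterion: mean
# AUC; ties broken by fewer boosting rounds, then smaller depth), then
# refitted on all training data. Ensembles over the six member scores:
# MEAN (arithmetic average), MAXIMUM (elementwise max) and STACKED (a
# logistic combiner trained on out-of-fold member scores).

#' Default hyperparameter grid
#'
#' @param eta,max_depth,gamma,nrounds candidate vectors.
#' @return data.frame, one row per grid cell.
#' @export
default_grid <- function(eta = c(0.05, 0.1, 0.3), max_depth = c(4, 6, 8),
                         gamma = c(0, 1), nrounds = c(100, 300)) {
  stopifnot(length(eta) > 0, length(max_depth) > 0, length(gamma) > 0,
            length(nrounds) > 0, all(max_depth >= 1), all(nrounds >= 1))
  expand.grid(eta = eta, max_depth = max_depth, gamma = gamma,
              nrounds = nrounds, KEEP.OUT.ATTRS = FALSE)
}

# Single-cell grid used by desk-scale evaluation runs.
#' @rdname default_grid
#' @export
fast_grid <- function() default_grid(eta = 0.1, max_depth = 5, gamma = 0,
                                     nrounds = 60)

tf_sparse <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  Matrix::Matrix(x, sparse = TRUE)
}

tf_dmatrix <- function(x, y = NULL) {
  xs <- tf_sparse(x)
  if (is.null(y)) xgboost::xgb.DMatrix(xs, nthread = 1)
  else xgboost::xgb.DMatrix(xs, label = y, nthread = 1)
}

tf_xgb_fit <- function(x, y, cfg, seed, nthread = 1) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  learning_rate = cfg$eta, max_depth = cfg$max_depth,
                  min_split_loss = cfg$gamma, tree_method = "hist",
                  max_bin = 63, nthread = nthread, seed = seed),
    data = tf_dmatrix(x, y), nrounds = cfg$nrounds, verbose = 0)
}

#' Train one scheme model by grid search
#'
#' @param x pair-feature matrix (rows = records).
#' @param y binary labels (0/1), both classes present.
#' @param grid hyperparameter grid (see [default_grid()]); a single-row
#'   grid skips the search.
#' @param seed integer master seed; all internal folds and fits derive
#'   deterministic sub-seeds from it.
#' @param scheme scheme tag stored on the model.
#' @param nfolds internal stratified CV folds (default 10).
#' @param nthread xgboost threads (default 1).
#' @return `tf_scheme_model`: booster, chosen hyperparameters, CV AUC,
#'   recorded feature length.
#' @export
grid_search_train <- function(x, y, grid = default_grid(), seed = 1L,
                              scheme = "scheme", nfolds = 10L, nthread = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels are single-class", call. = FALSE)
  x <- tf_sparse(x)
  if (!all(is.finite(x@x))) {
    nf <- which(!is.finite(as.matrix(x)), arr.ind = TRUE)
    stop("non-finite feature at row ", nf[1, 1], ", column ", nf[1, 2],
         call. = FALSE)
  }
  grid <- as.data.frame(grid)
  cv_auc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    fold <- tf_stratified_folds(y, nfolds, tf_subseed(seed, scheme, "cvfold"))
    for (gcell in seq_len(nrow(grid))) {
      aucs <- vapply(seq_len(nfolds), function(f) {
        tr <- fold != f; te <- !tr
        if (length(unique(y[te])) < 2) return(NA_real_)
        bst <- tf_xgb_fit(x[tr, , drop = FALSE], y[tr], grid[gcell, ],
                          tf_subseed(seed, scheme, gcell, f), nthread)
        roc_auc(y[te], predict(bst, tf_dmatrix(x[te, , drop = FALSE])))
      }, numeric(1))
      cv_auc[gcell] <- mean(aucs, na.rm = TRUE)
      gc(FALSE)
    }
    best <- order(-cv_auc, grid$nrounds, grid$max_depth)[1]
  } else best <- 1L
  cfg <- grid[best, ]
  booster <- tf_xgb_fit(x, y, cfg, tf_subseed(seed, scheme, "final"), nthread)
  structure(list(booster = booster, scheme = scheme,
                 params = as.list(cfg), cv_auc = cv_auc[best],
                 grid_auc = cv_auc, n_features = ncol(x)),
            class = "tf_scheme_model")
}

#' @export
print.tf_scheme_model <- function(x, ...) {
  cat("<tf_scheme_model> ", x$scheme, ": ", x$n_features, " features, ",
      "eta=", x$params$eta, " depth=", x$params$max_depth,
      " gamma=", x$params$gamma, " rounds=", x$params$nrounds,
      if (!is.na(x$cv_auc)) sprintf(" (CV AUC %.3f)", x$cv_auc), "\n", sep = "")
  invisible(x)
}

#' Score pair-feature rows with a scheme model
#'
#' @param model a `tf_scheme_model`.
#' @param pairs matrix whose width matches the model's recorded length.
#' @return probability vector in [0, 1].
#' @export
predict_scheme <- function(model, pairs) {
  if (ncol(pairs) != model$n_features)
    stop("pair length ", ncol(pairs), " does not match model manifest (",
         model$n_features, " features for ", model$scheme, ")", call. = FALSE)
  predict(model$booster, tf_dmatrix(pairs))
}

#' Fuse six member score vectors
#'
#' @param scores matrix (rows = samples, 6 columns) or list of six
#'   equal-length vectors.
#' @param strategy `"mean"`, `"max"` or `"stacked"`.
#' @param meta logistic-combiner coefficients (intercept + 6), required for
#'   `"stacked"`.
#' @return fused score vector in [0, 1].
#' @export
ensemble_scores <- function(scores, strategy = c("mean", "max", "stacked"),
                            meta = NULL) {
  strategy <- match.arg(strategy)
  if (is.list(scores) && !is.data.frame(scores)) {
    if (length(unique(lengths(scores))) != 1)
      stop("member score vectors differ in length", call. = FALSE)
    scores <- do.call(cbind, scores)
  }
  scores <- as.matrix(scores)
  switch(strategy,
         mean = rowMeans(scores),
         max = apply(scores, 1, max),
         stacked = {
           if (is.null(meta)) stop("stacked ensemble needs meta coefficients",
                                   call. = FALSE)
           eta <- meta[1] + as.numeric(scores %*% meta[-1])
           1 / (1 + exp(-eta))
         })
}

#' Train the full six-member ensemble system
#'
#' @param records labeled interaction records (aligned with `features`).
#' @param features named list over the six schemes; each element a list
#'   with `x` (pair matrix) and `y` (labels), all aligned to `records`
#'   (see [build_pair_features()]).
#' @param grid hyperparameter grid per member.
#' @param strategy ensemble fusion strategy.
#' @param seed master seed.
#' @param nthread xgboost threads.
#' @return `tf_ensemble`: six `tf_scheme_model`s, strategy, stacked-meta
#'   coefficients (when applicable), manifest.
#' @export
train_full_system <- function(records, features, grid = default_grid(),
                              strategy = c("mean", "max", "stacked"),
                              seed = 1L, nthread = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(setequal(names(features), .tf_schemes))
  y <- features[[1]]$y
  for (s in .tf_schemes)
    if (!identical(features[[s]]$y, y))
      stop("feature sets are not aligned to the same records", call. = FALSE)
  members <- lapply(.tf_schemes, function(s)
    grid_search_train(features[[s]]$x, y, grid, seed, scheme = s,
                      nthread = nthread))
  names(members) <- .tf_schemes
  meta <- NULL
  if (strategy == "stacked") {
    # out-of-fold member scores -> logistic combiner (no leakage)
    fold <- tf_stratified_folds(y, 5L, tf_subseed(seed, "stack"))
    oof <- matrix(NA_real_, length(y), length(.tf_schemes))
    for (f in 1:5) {
      te <- fold == f
      for (k in seq_along(.tf_schemes)) {
        s <- .tf_schemes[k]
        bst <- tf_xgb_fit(features[[s]]$x[!te, , drop = FALSE], y[!te],
                          as.data.frame(members[[s]]$params),
                          tf_subseed(seed, "stack", s, f), nthread)
        oof[te, k] <- predict(bst, tf_dmatrix(features[[s]]$x[te, , drop = FALSE]))
      }
    }
    fit <- stats::glm.fit(cbind(1, oof), y,
                          family = stats::binomial())
    meta <- as.numeric(fit$coefficients)
    meta[is.na(meta)] <- 0
  }
  structure(list(members = members, strategy = strategy, meta = meta,
                 seed = seed,
                 manifest = list(
                   schemes = .tf_schemes,
                   lengths = vapply(members, `[[`, numeric(1), "n_features"),
                   strategy = strategy, seed = seed,
                   version = as.character(utils::packageVersion("targetfisher")))),
            class = "tf_ensemble")
}

tf_member_scores <- function(ensemble, features) {
  vapply(.tf_schemes, function(s)
    predict_scheme(ensemble$members[[s]], features[[s]]),
    numeric(nrow(features[[1]])))
}
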