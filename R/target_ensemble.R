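# The user-facing fitting surface: target_ensemble() wires the full
# pipeline (aggregation, labeling, compound + protein featurization, six
# member models, fusion) into one fitted-model object with the usual
# print / summary / predict / plot methods. Prediction ranks the fixed
# target panel for arbitrary query compounds.

#' Fit an ensemble chemogenomic target-prediction model
#'
#' @param compounds a `tf_compounds` object ([read_compounds()]).
#' @param panel a `tf_panel` ([read_target_panel()]).
#' @param ontology a `tf_ontology` for the GO similarity matrices.
#' @param activities bioactivity measurements (`compound_id`, `target_id`,
#'   `ki_nM`), replicate rows allowed.
#' @param grid hyperparameter grid for every member ([default_grid()]).
#' @param strategy ensemble fusion: `"mean"` (default), `"max"`, `"stacked"`.
#' @param seed master seed controlling every stochastic step.
#' @param nthread xgboost threads.
#' @return object of class `target_ensemble`.
#' @export
target_ensemble <- function(compounds, panel, ontology, activities,
                            grid = default_grid(),
                            strategy = c("mean", "max", "stacked"),
                            seed = 1L, nthread = 1L) {
  strategy <- match.arg(strategy)
  records <- label_interactions(aggregate_bioactivities(activities))
  cf <- list(ECFP4 = featurize_compounds(compounds, "ECFP4"),
             MACCS = featurize_compounds(compounds, "MACCS"),
             MOL2D = featurize_compounds(compounds, "MOL2D"))
  proa <- compute_proa_panel(panel)
  prob <- compute_prob_panel(panel, ontology)
  pf <- list(PROA = proa, PROB = prob)
  features <- lapply(stats::setNames(.tf_schemes, .tf_schemes), function(s) {
    parts <- tf_scheme_parts(s)
    build_pair_features(records, cf[[parts$compound]], pf[[parts$protein]], s)
  })
  # align all six on the intersection of surviving records
  keys <- lapply(features, function(f)
    paste(f$records$compound_id, f$records$target_id))
  common <- Reduce(intersect, keys)
  for (s in .tf_schemes) {
    sel <- keys[[s]] %in% common
    features[[s]]$x <- features[[s]]$x[sel, , drop = FALSE]
    features[[s]]$y <- features[[s]]$y[sel]
    features[[s]]$records <- features[[s]]$records[sel, , drop = FALSE]
  }
  ens <- train_full_system(features[[1]]$records, features, grid = grid,
                           strategy = strategy, seed = seed, nthread = nthread)
  structure(list(ensemble = ens, proa = proa, prob = prob,
                 panel_ids = panel$ids, strategy = strategy, seed = seed,
                 n_records = length(features[[1]]$y),
                 n_positive = sum(features[[1]]$y),
                 mol2d_manifest = mol2d_manifest()),
            class = "target_ensemble")
}

# Member scores for a set of compounds against the whole panel.
# Returns list(scores = n_pairs x 6 matrix, compound_id, target_id).
tf_panel_scores <- function(object, compound_features) {
  panel_n <- length(object$panel_ids)
  protein <- list(PROA = object$proa$features, PROB = object$prob$features)
  ids <- rownames(compound_features[[1]])
  out <- matrix(NA_real_, nrow = length(ids) * panel_n, ncol = length(.tf_schemes),
                dimnames = list(NULL, .tf_schemes))
  for (s in .tf_schemes) {
    parts <- tf_scheme_parts(s)
    cfm <- compound_features[[parts$compound]]
    pm <- protein[[parts$protein]]
    big <- tf_sparse(do.call(rbind, lapply(seq_along(ids), function(i)
      enumerate_panel_pairs(cfm[i, ], pm))))
    out[, s] <- predict_scheme(object$ensemble$members[[s]], big)
    rm(big); gc(FALSE)
  }
  list(scores = out,
       compound_id = rep(ids, each = panel_n),
       target_id = rep(object$panel_ids, times = length(ids)))
}

#' Rank the target panel for query compounds
#'
#' @param object a fitted `target_ensemble`.
#' @param newdata a `tf_compounds` object, or a character vector of SMILES
#'   (optionally named by compound id).
#' @param top_k how many targets to report per compound (clipped to the
#'   panel size with a warning); default all.
#' @param ... unused.
#' @return data.frame with `compound_id`, `rank`, `target_id`, `score`,
#'   ranked by descending score (ties broken by target id).
#' @export
predict.target_ensemble <- function(object, newdata, top_k = NULL, ...) {
  if (!inherits(newdata, "tf_compounds")) {
    ids <- names(newdata) %||% sprintf("query%03d", seq_along(newdata))
    newdata <- parse_compounds(ids, unname(newdata))
  }
  panel_n <- length(object$panel_ids)
  if (is.null(top_k)) top_k <- panel_n
  if (top_k > panel_n) {
    warning("top_k clipped to panel size (", panel_n, ")", call. = FALSE)
    top_k <- panel_n
  }
  cf <- list(ECFP4 = featurize_compounds(newdata, "ECFP4"),
             MACCS = featurize_compounds(newdata, "MACCS"),
             MOL2D = featurize_compounds(newdata, "MOL2D"))
  common <- Reduce(intersect, lapply(cf, rownames))
  cf <- lapply(cf, function(m) m[common, , drop = FALSE])
  ps <- tf_panel_scores(object, cf)
  fused <- ensemble_scores(ps$scores, object$strategy, object$ensemble$meta)
  res <- do.call(rbind, lapply(split(seq_along(fused), ps$compound_id), function(idx) {
    ord <- idx[order(-fused[idx], ps$target_id[idx])][seq_len(top_k)]
    data.frame(compound_id = ps$compound_id[ord], rank = seq_len(top_k),
               target_id = ps$target_id[ord], score = fused[ord],
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' @export
print.target_ensemble <- function(x, ...) {
  cat("Ensemble chemogenomic target-prediction model\n")
  cat("  panel: ", length(x$panel_ids), " targets; training pairs: ",
      x$n_records, " (", x$n_positive, " positive)\n", sep = "")
  cat("  fusion: ", x$strategy, "; seed: ", x$seed, "\n", sep = "")
  for (m in x$ensemble$members) print(m)
  invisible(x)
}

#' @export
summary.target_ensemble <- function(object, ...) {
  memb <- data.frame(
    scheme = .tf_schemes,
    n_features = vapply(object$ensemble$members, `[[`, numeric(1), "n_features"),
    cv_auc = vapply(object$ensemble$members, `[[`, numeric(1), "cv_auc"),
    row.names = NULL)
  out <- list(members = memb, strategy = object$strategy,
              n_records = object$n_records, n_positive = object$n_positive,
              panel_size = length(object$panel_ids))
  class(out) <- "summary.target_ensemble"
  out
}

#' @export
print.summary.target_ensemble <- function(x, ...) {
  cat("target_ensemble:", x$n_records, "training pairs (",
      x$n_positive, "positive ) over", x$panel_size, "targets\n")
  print(x$members)
  invisible(x)
}

#' @export
plot.target_ensemble <- function(x, ...) {
  auc <- vapply(x$ensemble$members, `[[`, numeric(1), "cv_auc")
  if (all(is.na(auc))) {
    warning("no stored CV AUC (single-cell grid); nothing to plot",
            call. = FALSE)
    return(invisible(x))
  }
  graphics::barplot(auc, names.arg = .tf_schemes, las = 2,
                    ylab = "internal CV AUC", ylim = c(0, 1), ...)
  invisible(x)
}

#' Serialize / restore a fitted model bundle
#'
#' The bundle is a directory holding each member booster (xgboost binary),
#' the panel feature blocks, and a JSON manifest (schemes, feature lengths,
#' panel target ids, seed, package version).
#'
#' @param object a fitted `target_ensemble`.
#' @param dir bundle directory (created if missing).
#' @export
save_bundle <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in .tf_schemes)
    xgboost::xgb.save(object$ensemble$members[[s]]$booster,
                      file.path(dir, paste0(gsub("-", "_", s), ".ubj")))
  core <- object
  for (s in .tf_schemes) core$ensemble$members[[s]]$booster <- NULL
  saveRDS(core, file.path(dir, "model_core.rds"))
  manifest <- c(object$ensemble$manifest,
                list(panel_ids = object$panel_ids,
                     mol2d = mol2d_manifest()$name))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  object <- readRDS(file.path(dir, "model_core.rds"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$mol2d, mol2d_manifest()$name))
    stop("bundle Mol2D descriptor manifest disagrees with this package ",
         "version; refusing to predict", call. = FALSE)
  for (s in .tf_schemes)
    object$ensemble$members[[s]]$booster <-
      xgboost::xgb.load(file.path(dir, paste0(gsub("-", "_", s), ".ubj")))
  object
}
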