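# The evaluation protocol: stratified pair-split / compound-split 10-fold
# cross-validation with repetitions, classification metrics (ACC/SE/SP by
# the confusion-matrix formulas, AUC as the Mann-Whitney rank statistic),
# recall@k over full-panel target rankings, and enrichment folds relative
# to uniform random ranking.

#' Assign cross-validation folds
#'
#' Pair-split: records are stratified jointly by target and label; targets
#' with <= `small_target` records are forced into training everywhere
#' (fold 0). Compound-split: unique compounds are shuffled and divided into
#' `n_folds` parts; every record follows its compound.
#'
#' @param records labeled interaction records.
#' @param mode `"pair"` or `"compound"`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @param small_target forced-training threshold (default 5).
#' @return `tf_folds`: integer fold per record (0 = forced training).
#' @export
make_folds <- function(records, mode = c("pair", "compound"), n_folds = 10L,
                       seed = 1L, small_target = 5L) {
  mode <- match.arg(mode)
  n <- nrow(records)
  if (n < n_folds) stop("fewer records than folds", call. = FALSE)
  if (mode == "pair") {
    tcount <- table(records$target_id)
    forced <- records$target_id %in% names(tcount)[tcount <= small_target]
    fold <- integer(n)
    strata <- paste(records$target_id, records$label)
    fold[!forced] <- tf_stratified_folds(strata[!forced], n_folds,
                                         tf_subseed(seed, "pairfold"))
  } else {
    comp <- unique(records$compound_id)
    set.seed(tf_subseed(seed, "compfold"))
    comp <- comp[sample.int(length(comp))]
    cfold <- rep(seq_len(n_folds), length.out = length(comp))
    fold <- cfold[match(records$compound_id, comp)]
  }
  structure(list(fold = fold, mode = mode, n_folds = n_folds), class = "tf_folds")
}

#' Confusion-matrix classification metrics at a threshold
#'
#' @param labels binary labels (0/1), both classes present.
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return list with TP/FN/TN/FP counts and ACC, SE, SP, AUC.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("labels are single-class", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  list(TP = tp, FN = fn, TN = tn, FP = fp,
       ACC = (tp + tn) / (tp + tn + fp + fn),
       SE = tp / (tp + fn), SP = tn / (tn + fp),
       AUC = roc_auc(labels, scores))
}

#' Area under the ROC curve (Mann-Whitney rank statistic)
#'
#' Equals (concordant + 0.5 ties) / (P * N) over all positive-negative
#' score pairs.
#'
#' @inheritParams classification_metrics
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Recall@k over ranked target predictions
#'
#' @param rankings data.frame with `compound_id`, `target_id`, `rank`
#'   (full-panel ranking per test compound, ties already broken by target
#'   id).
#' @param positives data.frame of known positive test pairs
#'   (`compound_id`, `target_id`).
#' @param k ranking cutoff.
#' @param level `"pair"` (default): fraction of known positive pairs whose
#'   target ranks <= k; `"compound"`: fraction of compounds with at least
#'   one known target in the top k.
#' @return recall in percent.
#' @export
recall_at_k <- function(rankings, positives, k, level = c("pair", "compound")) {
  level <- match.arg(level)
  if (!nrow(positives)) return(NA_real_)
  miss <- setdiff(positives$compound_id, rankings$compound_id)
  if (length(miss))
    stop("no ranking for compound(s): ", paste(utils::head(miss, 3),
         collapse = ", "), call. = FALSE)
  key <- paste(rankings$compound_id, rankings$target_id)
  rk <- rankings$rank[match(paste(positives$compound_id, positives$target_id),
                            key)]
  hit <- !is.na(rk) & rk <= k
  if (level == "pair") 100 * mean(hit)
  else 100 * mean(vapply(split(hit, positives$compound_id), any, logical(1)))
}

#' Enrichment fold of a recall@k over random ranking
#'
#' fold = (recall/100) / (k / panel_size); e.g. recall 28.54% at k = 1 on
#' an 859-target panel is a 245-fold enrichment.
#'
#' @param recall_percent recall in percent (0-100).
#' @param k ranking cutoff (>= 1).
#' @param panel_size number of targets ranked.
#' @return list with `fold` (exact) and `fold_rounded`.
#' @export
enrichment_fold <- function(recall_percent, k, panel_size) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  stopifnot(recall_percent >= 0, recall_percent <= 100, k <= panel_size)
  fold <- (recall_percent / 100) / (k / panel_size)
  list(fold = fold, fold_rounded = round(fold))
}

#' Run the full cross-validated evaluation protocol
#'
#' Per repeat: fresh folds (repeat-specific sub-seed); per fold: the six
#' members and the ensemble are trained on the training split, the test
#' split is scored, and every test compound is ranked against the full
#' panel. Classification metrics are computed on the pooled out-of-fold
#' predictions of each repeat; recall@k on the pooled rankings. Aggregates
#' are mean and sd across repeats.
#'
#' @param records labeled interaction records.
#' @param features named list of six aligned pair-feature sets
#'   ([build_pair_features()]).
#' @param protein_features list with `PROA`, `PROB` feature blocks.
#' @param compound_features named list `ECFP4`/`MACCS`/`MOL2D` of compound
#'   feature matrices covering all record compounds.
#' @param panel_ids target ids, panel order.
#' @param mode `"pair"` or `"compound"` split.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 5).
#' @param grid member hyperparameter grid; the default single-cell
#'   [fast_grid()] skips tuning.
#' @param strategy ensemble fusion strategy.
#' @param seed master seed.
#' @param top_k_max largest ranking cutoff reported (default 10).
#' @param nthread xgboost threads.
#' @return `tf_cv_report`: per-repeat and aggregated classification and
#'   ranking metrics.
#' @export
run_cv <- function(records, features, protein_features, compound_features,
                   panel_ids, mode = c("pair", "compound"), n_folds = 10L,
                   n_repeats = 5L, grid = fast_grid(),
                   strategy = c("mean", "max", "stacked"), seed = 1L,
                   top_k_max = 10L, nthread = 1L) {
  mode <- match.arg(mode); strategy <- match.arg(strategy)
  y <- features[[1]]$y
  # sparse pair matrices: subsetting is cheap and xgboost takes them
  # without a dense copy (keeps the peak footprint bounded)
  for (s in names(features)) features[[s]]$x <- tf_sparse(features[[s]]$x)
  panel_n <- length(panel_ids)
  protein <- lapply(protein_features, function(p)
    if (inherits(p, c("tf_proa", "tf_prob"))) p$features else p)
  rep_class <- list(); rep_recall <- list(); rep_member_auc <- list()
  for (r in seq_len(n_repeats)) {
    rseed <- tf_subseed(seed, "repeat", r)
    folds <- make_folds(records, mode, n_folds, seed = rseed)
    stopifnot(all(tabulate(folds$fold[folds$fold > 0], folds$n_folds) >= 0))
    oof_scores <- rep(NA_real_, length(y))
    oof_member <- matrix(NA_real_, length(y), length(.tf_schemes))
    rank_rows <- list()
    for (f in seq_len(n_folds)) {
      te <- folds$fold == f
      tr <- !te
      if (!any(te)) next
      if (mode == "compound" &&
          length(intersect(records$compound_id[tr], records$compound_id[te])))
        stop("compound leakage across folds", call. = FALSE)
      members <- lapply(.tf_schemes, function(s)
        grid_search_train(features[[s]]$x[tr, , drop = FALSE], y[tr], grid,
                          tf_subseed(rseed, "fold", f), scheme = s,
                          nthread = nthread))
      names(members) <- .tf_schemes
      meta <- NULL
      if (strategy == "stacked") {
        sc_tr <- vapply(.tf_schemes, function(s)
          predict_scheme(members[[s]], features[[s]]$x[tr, , drop = FALSE]),
          numeric(sum(tr)))
        fitg <- stats::glm.fit(cbind(1, sc_tr), y[tr], family = stats::binomial())
        meta <- as.numeric(fitg$coefficients); meta[is.na(meta)] <- 0
      }
      sc <- vapply(.tf_schemes, function(s)
        predict_scheme(members[[s]], features[[s]]$x[te, , drop = FALSE]),
        numeric(sum(te)))
      if (sum(te) == 1) sc <- matrix(sc, nrow = 1)
      oof_member[te, ] <- sc
      oof_scores[te] <- ensemble_scores(sc, strategy, meta)
      # rank every test compound against the panel
      test_compounds <- unique(records$compound_id[te])
      member_big <- vapply(.tf_schemes, function(s) {
        parts <- tf_scheme_parts(s)
        cfm <- compound_features[[parts$compound]]
        pm <- protein[[parts$protein]]
        big <- tf_sparse(do.call(rbind, lapply(test_compounds, function(cid)
          enumerate_panel_pairs(cfm[cid, ], pm))))
        sc_big <- predict_scheme(members[[s]], big)
        rm(big); gc(FALSE)
        sc_big
      }, numeric(length(test_compounds) * panel_n))
      if (length(test_compounds) * panel_n == 1)
        member_big <- matrix(member_big, nrow = 1)
      fused <- ensemble_scores(member_big, strategy, meta)
      cid <- rep(test_compounds, each = panel_n)
      tid <- rep(panel_ids, times = length(test_compounds))
      # deterministic tie-break by target id: order within compound
      rank_rows[[length(rank_rows) + 1L]] <- do.call(rbind,
        lapply(split(seq_along(fused), cid), function(idx) {
          ord <- idx[order(-fused[idx], tid[idx])]
          data.frame(compound_id = cid[ord], target_id = tid[ord],
                     rank = seq_along(ord), score = fused[ord],
                     stringsAsFactors = FALSE)
        }))
      rm(members); gc(FALSE)
    }
    eval_idx <- !is.na(oof_scores)
    cm <- classification_metrics(y[eval_idx], oof_scores[eval_idx])
    rankings <- do.call(rbind, rank_rows)
    positives <- records[eval_idx & y == 1, c("compound_id", "target_id")]
    rec <- vapply(seq_len(top_k_max), function(k)
      recall_at_k(rankings, positives, k), numeric(1))
    member_auc <- vapply(seq_along(.tf_schemes), function(j)
      roc_auc(y[eval_idx], oof_member[eval_idx, j]), numeric(1))
    rep_class[[r]] <- cm
    rep_recall[[r]] <- rec
    rep_member_auc[[r]] <- member_auc
  }
  agg <- function(vals) c(mean = mean(vals), sd = if (length(vals) > 1) stats::sd(vals) else 0)
  class_agg <- sapply(c("ACC", "SE", "SP", "AUC"), function(mname)
    agg(vapply(rep_class, function(cm) cm[[mname]], numeric(1))))
  recall_mat <- do.call(rbind, rep_recall)
  recall_agg <- rbind(mean = colMeans(recall_mat),
                      sd = if (n_repeats > 1) apply(recall_mat, 2, stats::sd)
                           else rep(0, top_k_max))
  colnames(recall_agg) <- paste0("recall@", seq_len(top_k_max))
  enr <- vapply(seq_len(top_k_max), function(k)
    enrichment_fold(recall_agg["mean", k], k, panel_n)$fold, numeric(1))
  member_auc_mat <- do.call(rbind, rep_member_auc)
  colnames(member_auc_mat) <- .tf_schemes
  structure(list(mode = mode, n_folds = n_folds, n_repeats = n_repeats,
                 strategy = strategy, panel_size = panel_n,
                 classification = class_agg, recall = recall_agg,
                 enrichment = enr, member_auc = member_auc_mat,
                 per_repeat = list(classification = rep_class,
                                   recall = rep_recall)),
            class = "tf_cv_report")
}

#' @export
print.tf_cv_report <- function(x, ...) {
  cat("Cross-validated evaluation (", x$mode, "-split, ", x$n_folds,
      " folds x ", x$n_repeats, " repeats, ", x$strategy, " ensemble)\n",
      sep = "")
  cm <- x$classification
  cat(sprintf("  ACC %.3f±%.3f  SE %.3f±%.3f  SP %.3f±%.3f  AUC %.3f±%.3f\n",
              cm["mean", "ACC"], cm["sd", "ACC"], cm["mean", "SE"],
              cm["sd", "SE"], cm["mean", "SP"], cm["sd", "SP"],
              cm["mean", "AUC"], cm["sd", "AUC"]))
  for (k in c(1L, min(10L, ncol(x$recall)))) {
    cat(sprintf("  recall@%d = %.2f%% ± %.2f  (%.0f-fold enrichment)\n", k,
                x$recall["mean", k], x$recall["sd", k], x$enrichment[k]))
  }
  invisible(x)
}
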