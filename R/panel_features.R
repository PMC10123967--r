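# Panel-level protein feature blocks.
#
# ProA: seven raw descriptor groups per protein; every sub-group whose raw
# dimensionality exceeds 50 is PCA-compressed to min(50, N-1) components
# fitted on the panel itself (the panel is a fixed, closed prediction
# universe, identical at train and predict time, so panel-level fitting
# leaks nothing). Shipped group budget (rank-sufficient panel):
#   aac 20 | 8 x autocorrelation 90 -> 50 | ctd_c 21 | ctd_t 21 |
#   ctd_d 105 -> 50 | ctriad 343 -> 50 | socn 30 | qso 50 | paac 50 |
#   zwin_mean 35 | zwin_sd 35   == 762.
#
# ProB: rows of the four panel similarity matrices (SEQ, GO_BP, GO_MF,
# GO_CC), each PCA-compressed to min(50, N-1) -> 200 when N >= 51.

#' Compute the ProA feature block for a target panel
#'
#' @param panel a `tf_panel` (>= 2 proteins).
#' @param k PCA target dimensionality per sub-group (default 50).
#' @return `tf_proa` object: `features` (N x D matrix, D = 762 on a
#'   rank-sufficient panel), `projections` (fitted `tf_pca` per compressed
#'   sub-group), `manifest` (per-group raw and kept dimensions).
#' @export
compute_proa_panel <- function(panel, k = 50L) {
  if (length(panel$ids) < 2) stop("panel needs >= 2 proteins", call. = FALSE)
  raw <- tf_proa_raw_panel(panel)
  projections <- list()
  blocks <- list()
  manifest <- data.frame(group = character(0), raw = integer(0),
                         kept = integer(0), stringsAsFactors = FALSE)
  for (g in names(raw)) {
    mat <- raw[[g]]
    if (ncol(mat) > k) {
      proj <- fit_pca(mat, k)
      blocks[[g]] <- predict(proj, mat)
      colnames(blocks[[g]]) <- sprintf("%s_pc%02d", g, seq_len(proj$k))
      projections[[g]] <- proj
    } else {
      blocks[[g]] <- mat
      colnames(blocks[[g]]) <- sprintf("%s_%02d", g, seq_len(ncol(mat)))
    }
    manifest <- rbind(manifest, data.frame(group = g, raw = ncol(mat),
                                           kept = ncol(blocks[[g]])))
  }
  features <- do.call(cbind, blocks)
  rownames(features) <- panel$ids
  structure(list(features = features, projections = projections,
                 manifest = manifest, scheme = "PROA"), class = "tf_proa")
}

#' @export
print.tf_proa <- function(x, ...) {
  cat("<tf_proa> ", nrow(x$features), " proteins x ", ncol(x$features),
      " descriptors\n", sep = "")
  invisible(x)
}

#' Compute the ProB feature block for a target panel
#'
#' @param panel a `tf_panel`.
#' @param ontology a `tf_ontology` with the GO DAG.
#' @param k PCA components per similarity matrix (default 50).
#' @return `tf_prob` object: `features` (N x 4*min(k, N-1)), `projections`,
#'   `similarities` (the four raw matrices), `manifest`.
#' @export
compute_prob_panel <- function(panel, ontology, k = 50L) {
  n <- length(panel$ids)
  if (n < 2) stop("panel needs >= 2 proteins", call. = FALSE)
  sims <- list(SEQ = sequence_similarity_matrix(panel),
               GO_BP = go_similarity_matrix(panel, ontology, "BP"),
               GO_MF = go_similarity_matrix(panel, ontology, "MF"),
               GO_CC = go_similarity_matrix(panel, ontology, "CC"))
  projections <- list(); blocks <- list()
  manifest <- data.frame(group = character(0), raw = integer(0),
                         kept = integer(0), stringsAsFactors = FALSE)
  for (g in names(sims)) {
    proj <- fit_pca(sims[[g]], k)
    blocks[[g]] <- predict(proj, sims[[g]])
    colnames(blocks[[g]]) <- sprintf("%s_pc%02d", tolower(g), seq_len(proj$k))
    projections[[g]] <- proj
    manifest <- rbind(manifest, data.frame(group = g, raw = n,
                                           kept = proj$k))
  }
  features <- do.call(cbind, blocks)
  rownames(features) <- panel$ids
  structure(list(features = features, projections = projections,
                 similarities = sims, manifest = manifest, scheme = "PROB"),
            class = "tf_prob")
}

#' @export
print.tf_prob <- function(x, ...) {
  cat("<tf_prob> ", nrow(x$features), " proteins x ", ncol(x$features),
      " descriptors (4 similarity matrices)\n", sep = "")
  invisible(x)
}
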