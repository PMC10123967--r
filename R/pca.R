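# PCA compression used for descriptor sub-groups and similarity-matrix rows.
# Thin wrapper around stats::prcomp with a deterministic sign convention:
# within each component the loading element of largest magnitude is
# positive, so projections are reproducible across platforms.

#' Fit a PCA projection
#'
#' @param x numeric matrix, samples x features (>= 2 samples).
#' @param k number of components to retain; effective k is
#'   `min(k, ncol(x), nrow(x) - 1)`.
#' @return `tf_pca` object: `loadings` (features x k_eff), `center`,
#'   `k`, `explained` (variance fractions, non-increasing).
#' @export
fit_pca <- function(x, k) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  k_eff <- min(k, ncol(x), nrow(x) - 1L)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k_eff <- min(k_eff, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  tot <- sum(pc$sdev^2)
  explained <- if (tot > 0) (pc$sdev^2 / tot)[seq_len(k_eff)] else rep(0, k_eff)
  structure(list(loadings = rot, center = pc$center, k = k_eff,
                 explained = explained), class = "tf_pca")
}

#' @rdname fit_pca
#' @param object a fitted `tf_pca`.
#' @param newdata matrix with the same feature columns as the training data.
#' @param ... unused.
#' @export
predict.tf_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' @export
print.tf_pca <- function(x, ...) {
  cat("<tf_pca> ", nrow(x$loadings), " features -> ", x$k, " components (",
      sprintf("%.1f", 100 * sum(x$explained)), "% variance)\n", sep = "")
  invisible(x)
}
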