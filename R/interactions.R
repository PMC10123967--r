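# From raw bioactivity measurements to labeled modeling samples and
# chemogenomic pair-feature matrices.

#' Aggregate replicate Ki measurements per compound-target pair
#'
#' Pairs whose measurements span more than one order of magnitude
#' (max/min > 10) are excluded; the rest are summarized by the median.
#'
#' @param measurements data.frame with `compound_id`, `target_id`, `ki_nM`.
#' @return data.frame with one row per surviving pair.
#' @export
aggregate_bioactivities <- function(measurements) {
  if (!nrow(measurements))
    return(data.frame(compound_id = character(0), target_id = character(0),
                      ki_nM = numeric(0), stringsAsFactors = FALSE))
  stopifnot(all(measurements$ki_nM > 0))
  key <- paste(measurements$compound_id, measurements$target_id, sep = "\r")
  sp <- split(seq_len(nrow(measurements)), key)
  keep_rows <- lapply(sp, function(idx) {
    ki <- measurements$ki_nM[idx]
    if (max(ki) / min(ki) > 10) return(NULL)
    data.frame(compound_id = measurements$compound_id[idx[1]],
               target_id = measurements$target_id[idx[1]],
               ki_nM = stats::median(ki), stringsAsFactors = FALSE)
  })
  excluded <- sum(vapply(keep_rows, is.null, logical(1)))
  if (excluded > 0)
    tf_msg(excluded, " pair(s) excluded (replicate Ki spread > one order of magnitude)")
  out <- do.call(rbind, keep_rows[!vapply(keep_rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(compound_id = character(0), target_id = character(0),
                      ki_nM = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$compound_id, out$target_id), , drop = FALSE]
}

#' Label aggregated pairs at the 100 nM threshold
#'
#' Positive (label 1) iff Ki <= 100 nM; boundary inclusive.
#'
#' @param aggregated output of [aggregate_bioactivities()].
#' @param threshold_nM activity threshold (default 100).
#' @return the input with a `label` column (integer 0/1).
#' @export
label_interactions <- function(aggregated, threshold_nM = 100) {
  key <- paste(aggregated$compound_id, aggregated$target_id)
  if (anyDuplicated(key)) stop("aggregated pairs must be unique", call. = FALSE)
  aggregated$label <- as.integer(aggregated$ki_nM <= threshold_nM)
  tf_msg(sum(aggregated$label == 1L), " positives / ",
         sum(aggregated$label == 0L), " negatives at ", threshold_nM, " nM")
  aggregated
}

.tf_schemes <- c("ECFP4-ProA", "ECFP4-ProB", "Mol2D-ProA", "Mol2D-ProB",
                 "MACCS-ProA", "MACCS-ProB")

tf_scheme_parts <- function(scheme) {
  stopifnot(scheme %in% .tf_schemes)
  p <- strsplit(scheme, "-", fixed = TRUE)[[1]]
  list(compound = toupper(p[1]), protein = toupper(p[2]))
}

#' Assemble pair-feature rows for labeled interaction records
#'
#' Row i is the concatenation compound-block || protein-block of record i.
#'
#' @param records labeled interaction data.frame (`compound_id`,
#'   `target_id`, `label`).
#' @param compound_features matrix from [featurize_compounds()] (row names
#'   = compound ids) for the scheme's compound block.
#' @param protein_features matrix (row names = target ids): `$features` of
#'   a `tf_proa` / `tf_prob`, or the matrix itself.
#' @param scheme one of the six pair schemes, e.g. `"ECFP4-ProA"`.
#' @return list with `x` (matrix), `y` (labels), `records` (surviving rows).
#' @export
build_pair_features <- function(records, compound_features, protein_features,
                                scheme) {
  if (inherits(protein_features, c("tf_proa", "tf_prob")))
    protein_features <- protein_features$features
  parts <- tf_scheme_parts(scheme)
  expected <- c(ECFP4 = 1024L, MACCS = 166L, MOL2D = 188L)[[parts$compound]]
  if (ncol(compound_features) != expected)
    stop("compound feature width ", ncol(compound_features),
         " does not match scheme ", scheme, " (expected ", expected, ")",
         call. = FALSE)
  ci <- match(records$compound_id, rownames(compound_features))
  ti <- match(records$target_id, rownames(protein_features))
  ok <- !is.na(ci) & !is.na(ti)
  if (!any(ok))
    stop("no records with both compound and target features (scheme ",
         scheme, ")", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " record(s) dropped: missing compound or target ",
            "features", call. = FALSE)
  x <- cbind(compound_features[ci[ok], , drop = FALSE],
             protein_features[ti[ok], , drop = FALSE])
  rownames(x) <- NULL
  list(x = x, y = records$label[ok], records = records[ok, , drop = FALSE],
       scheme = scheme)
}

#' Pair-feature rows of one compound against the whole panel
#'
#' @param compound_row numeric vector: the compound's feature block.
#' @param protein_features protein block matrix (or `tf_proa`/`tf_prob`).
#' @return matrix with one row per panel target, in panel order.
#' @export
enumerate_panel_pairs <- function(compound_row, protein_features) {
  if (inherits(protein_features, c("tf_proa", "tf_prob")))
    protein_features <- protein_features$features
  n <- nrow(protein_features)
  x <- cbind(matrix(rep(compound_row, each = n), nrow = n), protein_features)
  colnames(x) <- c(names(compound_row), colnames(protein_features))
  rownames(x) <- rownames(protein_features)
  x
}
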