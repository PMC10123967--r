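#' @keywords internal
"_PACKAGE"

# Deterministic fan-out of a master seed into per-task sub-seeds.
# Kept below 2^31 so the result is always a valid R integer seed.
tf_subseed <- function(seed, ...) {
  tags <- vapply(list(...), as.character, character(1))
  h <- sum(utf8ToInt(paste(tags, collapse = "/")) * seq_along(utf8ToInt(paste(tags, collapse = "/"))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}

tf_msg <- function(...) message("[targetfisher] ", ...)

# Tab-separated reader used for every tabular input: UTF-8, '#' comments,
# header handling decided by the caller.
tf_read_tsv <- function(path, header = TRUE, col.names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, quote = "", fileEncoding = "UTF-8"),
    error = function(e) stop("unreadable file '", path, "': ", conditionMessage(e), call. = FALSE))
  if (!is.null(col.names) && !header) names(df) <- col.names[seq_len(ncol(df))]
  df
}

tf_write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE))
  invisible(ok)
}

# Stratified fold assignment: within every stratum, shuffled round-robin.
# Returns integer fold ids aligned with `strata`.
tf_stratified_folds <- function(strata, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(strata))
  start <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
    start <- start + length(idx)
  }
  fold
}
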