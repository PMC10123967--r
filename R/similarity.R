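# Panel-wide protein similarity matrices for the ProB block:
# (1) global sequence alignment similarity (BLOSUM62, gap open 10 /
#     extend 0.5), normalized S(a,b)/sqrt(S(a,a) S(b,b)) and clipped to
#     [0, 1];
# (2) Resnik GO semantic similarity per aspect (BP / MF / CC) with
#     best-match-average mixing, information content estimated from the
#     panel's own annotation corpus.

#' Pairwise global sequence similarity over a panel
#'
#' @param panel a `tf_panel`.
#' @return symmetric N x N matrix, unit diagonal, entries in [0, 1].
#' @export
sequence_similarity_matrix <- function(panel) {
  n <- length(panel$ids)
  if (n < 2) stop("panel needs >= 2 proteins", call. = FALSE)
  seqs <- Biostrings::AAStringSet(panel$sequences)
  names(seqs) <- panel$ids
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  self <- vapply(seq_len(n), function(i)
    sum(B62[cbind(strsplit(panel$sequences[i], "")[[1]],
                  strsplit(panel$sequences[i], "")[[1]])]), numeric(1))
  S <- matrix(0, n, n, dimnames = list(panel$ids, panel$ids))
  diag(S) <- 1
  for (i in seq_len(n - 1)) {
    sc <- Biostrings::pairwiseAlignment(
      rep(seqs[i], n - i), seqs[(i + 1):n],
      substitutionMatrix = B62, gapOpening = 10, gapExtension = 0.5,
      type = "global", scoreOnly = TRUE)
    sim <- pmin(1, pmax(0, sc / sqrt(self[i] * self[(i + 1):n])))
    S[i, (i + 1):n] <- sim
    S[(i + 1):n, i] <- sim
  }
  S
}

# Information content per term within one aspect: IC(t) = -ln p(t) with
# p(t) = (annotations of t or its descendants) / (total annotations).
tf_go_ic <- function(panel, ontology, aspect) {
  ann <- lapply(panel$go_terms, function(g) unique(g[[aspect]]))
  all_terms <- unlist(ann)
  total <- length(all_terms)
  if (total == 0) return(NULL)
  counts <- table(all_terms)
  g <- ontology$graph
  known <- names(counts)[names(counts) %in% ontology$terms]
  ics <- vapply(ontology$terms, function(t) {
    desc <- igraph::subcomponent(g, t, mode = "in")$name  # t and descendants
    cnt <- sum(counts[names(counts) %in% desc])
    if (cnt == 0) return(NA_real_)
    -log(cnt / total)
  }, numeric(1))
  names(ics) <- ontology$terms
  ics
}

tf_term_ancestors <- function(ontology, term) {
  if (!term %in% ontology$terms) return(character(0))
  igraph::subcomponent(ontology$graph, term, mode = "out")$name
}

#' Resnik GO semantic similarity matrix for one aspect
#'
#' Term-pair similarity is the information content of the most informative
#' common ancestor, normalized by the maximum IC in the aspect; protein
#' similarity is the best-match average over annotation sets. Proteins with
#' no annotations in the aspect have similarity 0 to all others and 1 to
#' themselves.
#'
#' @param panel a `tf_panel`.
#' @param ontology a `tf_ontology`.
#' @param aspect `"BP"`, `"MF"` or `"CC"`.
#' @return symmetric N x N matrix, unit diagonal, entries in [0, 1].
#' @export
go_similarity_matrix <- function(panel, ontology, aspect = c("BP", "MF", "CC")) {
  aspect <- match.arg(aspect)
  n <- length(panel$ids)
  S <- diag(1, n)
  dimnames(S) <- list(panel$ids, panel$ids)
  ics <- tf_go_ic(panel, ontology, aspect)
  if (is.null(ics) || all(is.na(ics)) || max(ics, na.rm = TRUE) <= 0) {
    warning("aspect ", aspect, " has no informative annotations; ",
            "similarity matrix is the identity", call. = FALSE)
    return(S)
  }
  maxic <- max(ics, na.rm = TRUE)
  terms <- unique(unlist(lapply(panel$go_terms, function(g) g[[aspect]])))
  terms <- terms[terms %in% ontology$terms]
  anc <- lapply(terms, function(t) tf_term_ancestors(ontology, t))
  names(anc) <- terms
  nt <- length(terms)
  TS <- matrix(0, nt, nt, dimnames = list(terms, terms))
  for (i in seq_len(nt)) for (j in i:nt) {
    common <- intersect(anc[[i]], anc[[j]])
    v <- if (length(common)) max(0, max(ics[common], na.rm = TRUE)) / maxic else 0
    TS[i, j] <- v; TS[j, i] <- v
  }
  sets <- lapply(panel$go_terms, function(g) intersect(g[[aspect]], terms))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    t1 <- sets[[i]]; t2 <- sets[[j]]
    if (!length(t1) || !length(t2)) next
    sub <- TS[t1, t2, drop = FALSE]
    bma <- (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
      (length(t1) + length(t2))
    S[i, j] <- bma; S[j, i] <- bma
  }
  S
}
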