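# Compound fingerprints: ECFP4 (1024 bits) and MACCS keys (166 bits).
#
# ECFP4 — the extended-connectivity circular fingerprint of bond diameter 4
# (radius 2) — is computed in-package on the tf_mol heavy-atom graph with
# the standard Morgan construction: per-atom initial invariants, two rounds
# of iterative neighbourhood hashing over sorted (bond, neighbour-id)
# lists, structural deduplication by environment bond set, identifiers
# folded modulo 1024. Sorting the neighbour lists makes the result
# invariant to atom order; hashing is a plain polynomial hash, so vectors
# are reproducible across platforms. MACCS keys are the public 166
# substructure definitions, computed by OpenBabel.

.tf_ob_fingerprint <- function(smiles, name) {
  src <- paste0(paste(smiles, collapse = "\n"), "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, name)
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (nrow(fp) != length(smiles))
    stop("fingerprint batch size mismatch (", nrow(fp), " vs ",
         length(smiles), ")", call. = FALSE)
  fp
}

# Deterministic polynomial hash of an integer vector into [0, 2^31 - 43).
tf_hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483587)) %% 2147483587
  h
}

# Circular (Morgan) fingerprint of one tf_mol, radius 2, folded length bits.
tf_morgan_bits <- function(mol, radius = 2L, nbits = 1024L) {
  n <- mol$n_heavy
  bd <- mol$bonds
  at <- mol$atoms
  z <- unname(.tf_atomic_number[at$elem]); z[is.na(z)] <- 0
  # ring membership per atom (cyclomatic shortcut via bridge test is done
  # in mol2d; here a cheap approximation: atom is in a ring iff it lies on
  # a cycle, detected from the graph)
  g <- tf_mol_graph(mol)
  in_ring <- rep(FALSE, n)
  if (nrow(bd) - n + igraph::components(g)$no > 0) {
    # only graphs with cycles need the test
    for (v in seq_len(n)) {
      nb <- c(bd$a2[bd$a1 == v], bd$a1[bd$a2 == v])
      if (length(nb) < 2) next
      g2 <- igraph::delete_vertices(g, v)
      d <- igraph::distances(g2, v = as.character(nb[1]),
                             to = as.character(nb[-1]))
      in_ring[v] <- any(is.finite(d))
    }
  }
  ids <- vapply(seq_len(n), function(a) tf_hash_ints(c(
    z[a], at$degree[a], at$nH[a], as.integer(at$aromatic[a]),
    as.integer(in_ring[a]), round(2 * sum(bd$order[bd$a1 == a | bd$a2 == a])))),
    numeric(1))
  nbr <- lapply(seq_len(n), function(a) {
    k <- which(bd$a1 == a | bd$a2 == a)
    other <- ifelse(bd$a1[k] == a, bd$a2[k], bd$a1[k])
    list(atoms = other, bonds = k, order = round(2 * bd$order[k]))
  })
  feats <- ids                       # radius-0 identifiers, all kept
  env_bonds <- lapply(seq_len(n), function(a) integer(0))
  seen_sets <- character(0)
  alive <- rep(TRUE, n)
  for (r in seq_len(radius)) {
    new_ids <- ids
    new_env <- env_bonds
    for (a in seq_len(n)) {
      if (!alive[a] || !length(nbr[[a]]$atoms)) { alive[a] <- FALSE; next }
      ord <- order(nbr[[a]]$order, ids[nbr[[a]]$atoms])
      new_ids[a] <- tf_hash_ints(c(r, ids[a],
                                   rbind(nbr[[a]]$order[ord],
                                         ids[nbr[[a]]$atoms[ord]])))
      grown <- sort(unique(c(env_bonds[[a]],
                             unlist(lapply(nbr[[a]]$atoms, function(u)
                               env_bonds[[u]])), nbr[[a]]$bonds)))
      if (identical(grown, env_bonds[[a]])) { alive[a] <- FALSE; next }
      new_env[[a]] <- grown
      key <- paste(grown, collapse = ",")
      if (key %in% seen_sets) next   # same environment already encoded
      seen_sets <- c(seen_sets, key)
      feats <- c(feats, new_ids[a])
    }
    ids <- new_ids
    env_bonds <- new_env
    if (!any(alive)) break
  }
  bits <- unique(as.integer(unique(feats) %% nbits)) + 1L
  v <- integer(nbits)
  v[bits] <- 1L
  v
}

#' Compute the ECFP4 fingerprint (1024 bits)
#'
#' @param x a `tf_compounds` object.
#' @return binary matrix, one row per compound, 1024 columns.
#' @export
compute_ecfp4 <- function(x) {
  stopifnot(inherits(x, "tf_compounds"))
  fp <- t(vapply(x$mols, tf_morgan_bits, integer(1024L)))
  colnames(fp) <- sprintf("ecfp4_%04d", seq_len(1024L))
  rownames(fp) <- x$ids
  fp
}

#' Compute the MACCS key fingerprint (166 bits)
#'
#' @inheritParams compute_ecfp4
#' @return binary matrix, one row per compound, 166 columns.
#' @export
compute_maccs <- function(x) {
  smiles <- if (inherits(x, "tf_compounds")) x$smiles else x
  fp <- .tf_ob_fingerprint(smiles, "MACCS")[, 1:166, drop = FALSE]
  storage.mode(fp) <- "integer"
  colnames(fp) <- sprintf("maccs_%03d", seq_len(166L))
  rownames(fp) <- if (inherits(x, "tf_compounds")) x$ids else NULL
  fp
}

#' Featurize compounds under one descriptor scheme
#'
#' @param compounds a `tf_compounds` object.
#' @param scheme one of `"ECFP4"`, `"MACCS"`, `"MOL2D"`.
#' @return numeric matrix, one row per compound (row names = compound ids).
#'   Compounds whose descriptor computation fails are dropped with a
#'   warning; it is fatal if none survive.
#' @export
featurize_compounds <- function(compounds, scheme = c("ECFP4", "MACCS", "MOL2D")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(compounds, "tf_compounds"))
  if (!length(compounds$ids)) stop("no compounds to featurize", call. = FALSE)
  mat <- switch(scheme,
                ECFP4 = compute_ecfp4(compounds),
                MACCS = compute_maccs(compounds),
                MOL2D = compute_mol2d_matrix(compounds))
  bad <- apply(mat, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    warning(sum(bad), " compound(s) produced non-finite ", scheme,
            " values and were dropped: ",
            paste(utils::head(rownames(mat)[bad], 5), collapse = ", "),
            call. = FALSE)
    mat <- mat[!bad, , drop = FALSE]
  }
  if (!nrow(mat)) stop("all compounds failed ", scheme, " featurization",
                       call. = FALSE)
  mat
}
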