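# Compound structures.
#
# All structure handling is delegated to OpenBabel (through ChemmineOB):
# input SMILES are canonicalized once, and the molecular graph (atoms with
# SYBYL types, bonds with orders, Gasteiger partial charges) is taken from a
# single SMILES -> MOL2 conversion parsed with bio3d. Every descriptor in the
# package works off the resulting `tf_mol` graph, which makes descriptor
# values independent of how the input SMILES was spelled.

# SYBYL atom-type -> standard bonding valence, used to infer implicit
# hydrogen counts (mol2 from SMILES carries no explicit hydrogens).
.tf_sybyl_valence <- c(
  "C.3" = 4, "C.2" = 4, "C.1" = 4, "C.ar" = 4, "C.cat" = 4,
  "N.3" = 3, "N.2" = 3, "N.1" = 3, "N.ar" = 3, "N.am" = 3, "N.pl3" = 3, "N.4" = 4,
  "O.3" = 2, "O.2" = 2, "O.co2" = 2, "S.3" = 2, "S.2" = 2, "S.o" = 4, "S.o2" = 6,
  "P.3" = 5, "F" = 1, "Cl" = 1, "Br" = 1, "I" = 1, "H" = 1)

# Canonicalize a vector of SMILES with OpenBabel; returns NA where parsing
# failed. Ids are threaded through as SMILES titles so that dropped
# molecules can be matched back to their inputs.
tf_canonical_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%06d", seq_along(smiles))
  src <- paste0(smiles, " ", ids, collapse = "\n")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n"))),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", character(1)))
  res <- rep(NA_character_, length(smiles))
  hit <- match(ids, ttl)
  res[!is.na(hit)] <- can[hit[!is.na(hit)]]
  # OpenBabel aborts a batch at the first unparseable SMILES; retry the
  # unmatched entries one at a time so later valid molecules survive
  if (length(smiles) > 1) {
    for (j in which(is.na(hit))) {
      one <- tryCatch(
        suppressWarnings(ChemmineOB::convertFormat(
          "SMI", "CAN", paste0(smiles[j], " x\n"))),
        error = function(e) "")
      one <- strsplit(one, "\t", fixed = TRUE)[[1]][1]
      if (!is.na(one) && nzchar(trimws(one))) res[j] <- trimws(one)
    }
  }
  res
}

# Keep the largest covalently bonded fragment (standardization default:
# salts / counter-ions are stripped; formal charges are kept as drawn).
tf_largest_fragment <- function(canonical) {
  vapply(canonical, function(s) {
    if (is.na(s) || !grepl(".", s, fixed = TRUE)) return(s)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    # heavy-atom count by SMILES atom tokens (bracket atoms, two-letter
    # halogens, organic subset), enough to pick the largest fragment
    n <- vapply(frags, function(f) {
      f2 <- gsub("\\[[^]]*H[^]]*\\]", "[X]", f)
      length(gregexpr("\\[[^]]+\\]|Cl|Br|si|se|[BCNOPSFI]|[bcnops]", f2)[[1]])
    }, integer(1))
    frags[which.max(n)]
  }, character(1), USE.NAMES = FALSE)
}

# Split a multi-molecule MOL2 string (as written by OpenBabel) into per-
# molecule atom/bond tables. The format here is machine-generated with a
# fixed section layout, so a direct reader is dependable.
tf_read_mol2 <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- which(lines == "@<TRIPOS>MOLECULE")
  lapply(seq_along(starts), function(i) {
    end <- if (i < length(starts)) starts[i + 1] - 1L else length(lines)
    blk <- lines[starts[i]:end]
    name <- trimws(blk[2])
    a0 <- which(blk == "@<TRIPOS>ATOM")
    b0 <- which(blk == "@<TRIPOS>BOND")
    sec_end <- function(from) {
      nxt <- which(startsWith(blk, "@<TRIPOS>") & seq_along(blk) > from)
      if (length(nxt)) min(nxt) - 1L else length(blk)
    }
    section <- function(from) {
      to <- sec_end(from)
      if (to <= from) return(character(0))
      ln <- blk[(from + 1):to]
      ln[nzchar(trimws(ln))]
    }
    af <- strsplit(trimws(section(a0)), "\\s+")
    bf <- strsplit(trimws(section(b0)), "\\s+")
    list(name = name,
         atom = data.frame(
           elety = vapply(af, `[`, character(1), 6L),
           charge = as.numeric(vapply(af, `[`, character(1), 9L)),
           stringsAsFactors = FALSE),
         bond = data.frame(
           origin = as.integer(vapply(bf, `[`, character(1), 2L)),
           target = as.integer(vapply(bf, `[`, character(1), 3L)),
           type = vapply(bf, `[`, character(1), 4L),
           stringsAsFactors = FALSE))
  })
}

# Parse canonical SMILES into tf_mol graphs via one batched MOL2 conversion.
tf_mol_from_smiles <- function(canonical, ids) {
  stopifnot(length(canonical) == length(ids))
  src <- paste0(canonical, " ", ids, collapse = "\n")
  mol2 <- suppressWarnings(ChemmineOB::convertFormat("SMI", "MOL2", paste0(src, "\n")))
  mols <- tf_read_mol2(mol2)
  out <- rep(list(NULL), length(ids))
  names(out) <- ids
  for (m in mols) {
    j <- match(m$name, ids)
    if (is.na(j)) next
    out[[j]] <- tf_mol_from_mol2(m, canonical[j])
  }
  out
}

tf_mol_from_mol2 <- function(m, smiles) {
  at <- m$atom
  bd <- m$bond
  elem <- sub("\\..*$", "", at$elety)
  keep <- elem != "H"
  h_explicit <- integer(sum(keep))
  if (any(!keep)) {
    # fold explicit hydrogens (rare) into their heavy neighbour
    hidx <- which(!keep)
    for (h in hidx) {
      nb <- c(bd$target[bd$origin == h], bd$origin[bd$target == h])
      nb <- nb[keep[nb]][1]
      if (!is.na(nb)) h_explicit[sum(keep[seq_len(nb)])] <-
          h_explicit[sum(keep[seq_len(nb)])] + 1L
    }
    remap <- cumsum(keep)
    bd <- bd[keep[bd$origin] & keep[bd$target], , drop = FALSE]
    bd$origin <- remap[bd$origin]; bd$target <- remap[bd$target]
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  n <- nrow(at)
  type <- at$elety
  aromatic <- grepl("\\.ar$", type)
  border <- vapply(as.character(bd$type), function(t)
    switch(t, "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, "am" = 1, 1), numeric(1))
  deg <- tabulate(c(bd$origin, bd$target), nbins = n)
  bsum <- numeric(n)
  for (k in seq_len(nrow(bd))) {
    bsum[bd$origin[k]] <- bsum[bd$origin[k]] + border[k]
    bsum[bd$target[k]] <- bsum[bd$target[k]] + border[k]
  }
  val <- unname(.tf_sybyl_valence[type])
  val[is.na(val)] <- ceiling(bsum[is.na(val)])
  implicit_h <- pmax(0L, as.integer(round(val - round(bsum + 1e-9))))
  implicit_h <- implicit_h + h_explicit
  structure(list(
    smiles = smiles,
    atoms = data.frame(elem = elem, sybyl = type, aromatic = aromatic,
                       charge = at$charge, degree = deg, nH = implicit_h,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = bd$origin, a2 = bd$target,
                       order = border, type = as.character(bd$type),
                       stringsAsFactors = FALSE),
    n_heavy = n), class = "tf_mol")
}

#' @export
print.tf_mol <- function(x, ...) {
  cat("<tf_mol> ", x$smiles, " (", x$n_heavy, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Parse compound structures from SMILES
#'
#' Standardizes (largest fragment), canonicalizes and parses a vector of
#' SMILES. Unparseable entries are dropped with a warning; order of the
#' survivors is preserved.
#'
#' @param ids character vector of compound identifiers (must be unique).
#' @param smiles character vector of SMILES strings, same length.
#' @param standardize keep only the largest covalent fragment (default TRUE).
#' @return A `tf_compounds` object: list with `ids`, `smiles` (canonical)
#'   and `mols` (list of `tf_mol` graphs), parallel vectors.
#' @export
parse_compounds <- function(ids, smiles, standardize = TRUE) {
  stopifnot(length(ids) == length(smiles))
  if (anyDuplicated(ids))
    stop("duplicate compound_id: ", ids[duplicated(ids)][1], call. = FALSE)
  can <- tf_canonical_smiles(smiles, ids)
  if (standardize) {
    can <- tf_largest_fragment(can)
    redo <- !is.na(can) & grepl("[.]", can)
    can[redo] <- tf_canonical_smiles(can[redo], ids[redo])
  }
  ok <- !is.na(can) & nzchar(can)
  if (!any(ok)) stop("zero compounds parsed", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " compound(s) failed to parse and were dropped: ",
            paste(utils::head(ids[!ok], 5), collapse = ", "), call. = FALSE)
  mols <- tf_mol_from_smiles(can[ok], ids[ok])
  parsed <- !vapply(mols, is.null, logical(1))
  if (any(!parsed))
    warning(sum(!parsed), " compound(s) failed mol2 conversion: ",
            paste(utils::head(ids[ok][!parsed], 5), collapse = ", "), call. = FALSE)
  keep <- which(ok)[parsed]
  if (!length(keep)) stop("zero compounds parsed", call. = FALSE)
  structure(list(ids = ids[keep], smiles = can[keep], mols = mols[parsed],
                 n_rejected = length(ids) - length(keep)),
            class = "tf_compounds")
}

#' @export
print.tf_compounds <- function(x, ...) {
  cat("<tf_compounds> ", length(x$ids), " compounds",
      if (x$n_rejected) paste0(" (", x$n_rejected, " rejected)"), "\n", sep = "")
  invisible(x)
}

#' @export
length.tf_compounds <- function(x) length(x$ids)

#' @export
`[.tf_compounds` <- function(x, i) {
  structure(list(ids = x$ids[i], smiles = x$smiles[i], mols = x$mols[i],
                 n_rejected = 0L), class = "tf_compounds")
}
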