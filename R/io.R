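# Readers and writers for the pipeline's external formats.
# Tabular files are TSV (tab separator, UTF-8, '#' comment lines ignored).

#' Read compounds from a SMILES table or SDF file
#'
#' SMILES tables have two columns, `compound_id` and `smiles` (header
#' optional). SDF files are converted to SMILES with OpenBabel first, taking
#' the molecule title as the compound id.
#'
#' @param path input file.
#' @param format `"smiles"` (default) or `"sdf"`.
#' @param header does the SMILES table have a header line?
#' @param standardize keep only the largest covalent fragment.
#' @return `tf_compounds` (see [parse_compounds()]).
#' @export
read_compounds <- function(path, format = c("smiles", "sdf"), header = TRUE,
                           standardize = TRUE) {
  format <- match.arg(format)
  if (format == "sdf") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    out <- tempfile(fileext = ".smi")
    ChemmineOB::convertFormatFile("SDF", "SMI", path, out)
    lines <- readLines(out)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(compound_id = vapply(parts, function(p) p[max(2, length(p))], ""),
                     smiles = vapply(parts, `[`, "", 1L), stringsAsFactors = FALSE)
  } else {
    df <- tf_read_tsv(path, header = header, col.names = c("compound_id", "smiles"))
    if (ncol(df) < 2) stop("SMILES table needs two columns (id, smiles)", call. = FALSE)
    names(df)[1:2] <- c("compound_id", "smiles")
  }
  if (nrow(df) == 0) stop("zero compounds in ", path, call. = FALSE)
  parse_compounds(as.character(df$compound_id), as.character(df$smiles),
                  standardize = standardize)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the target panel: sequences, GO annotations and the ontology
#'
#' @param fasta amino-acid FASTA; record ids are the target ids.
#' @param go_annotations TSV with columns `protein_id`, `go_term`, `aspect`
#'   (aspect in BP/MF/CC). May be empty (header only).
#' @param ontology TSV edge list `child`, `parent` (directed child -> parent).
#' @param nonstandard policy for residues outside the 20-letter alphabet:
#'   they are dropped for composition-type descriptors; a sequence with more
#'   than `max_nonstandard_frac` such residues is fatal.
#' @param max_nonstandard_frac see above (default 0.05).
#' @return list with `panel` (a `tf_panel`: ids, sequences, go_terms) and
#'   `ontology` (a `tf_ontology`: igraph DAG).
#' @export
read_target_panel <- function(fasta, go_annotations, ontology,
                              max_nonstandard_frac = 0.05) {
  seqs <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  sq <- as.character(seqs)
  panel <- make_panel(ids, sq, max_nonstandard_frac = max_nonstandard_frac)

  ann <- tf_read_tsv(go_annotations, header = TRUE)
  if (ncol(ann) >= 3) {
    names(ann)[1:3] <- c("protein_id", "go_term", "aspect")
    unknown <- !(ann$protein_id %in% ids)
    if (any(unknown)) {
      warning(sum(unknown), " GO annotation row(s) reference proteins absent ",
              "from the FASTA and were dropped", call. = FALSE)
      ann <- ann[!unknown, , drop = FALSE]
    }
    for (i in seq_len(nrow(ann))) {
      a <- toupper(ann$aspect[i])
      if (!a %in% c("BP", "MF", "CC")) next
      j <- match(ann$protein_id[i], panel$ids)
      panel$go_terms[[j]][[a]] <- union(panel$go_terms[[j]][[a]],
                                        as.character(ann$go_term[i]))
    }
  }
  ont <- read_ontology(ontology)
  list(panel = panel, ontology = ont)
}

#' Construct a target panel from sequences in memory
#' @param ids,sequences parallel character vectors.
#' @param go_terms optional list (per protein) of lists keyed BP/MF/CC.
#' @param max_nonstandard_frac fatal threshold for non-canonical residues.
#' @export
make_panel <- function(ids, sequences, go_terms = NULL,
                       max_nonstandard_frac = 0.05) {
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("duplicate target_id", call. = FALSE)
  sequences <- toupper(sequences)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  clean <- vapply(seq_along(sequences), function(i) {
    ch <- strsplit(sequences[i], "")[[1]]
    bad <- !(ch %in% aa20)
    if (mean(bad) > max_nonstandard_frac)
      stop("sequence '", ids[i], "' has >", 100 * max_nonstandard_frac,
           "% non-canonical residues", call. = FALSE)
    paste(ch[!bad], collapse = "")
  }, character(1))
  short <- nchar(clean) < 30
  if (any(short))
    stop("sequence(s) shorter than 30 residues: ",
         paste(ids[short], collapse = ", "), call. = FALSE)
  if (is.null(go_terms))
    go_terms <- rep(list(list(BP = character(0), MF = character(0),
                              CC = character(0))), length(ids))
  structure(list(ids = ids, sequences = clean, go_terms = go_terms),
            class = "tf_panel")
}

#' @export
print.tf_panel <- function(x, ...) {
  nann <- sum(vapply(x$go_terms, function(g) sum(lengths(g)), numeric(1)))
  cat("<tf_panel> ", length(x$ids), " targets, sequence lengths ",
      min(nchar(x$sequences)), "-", max(nchar(x$sequences)),
      ", ", nann, " GO annotations\n", sep = "")
  invisible(x)
}

#' @export
length.tf_panel <- function(x) length(x$ids)

#' Read an ontology edge list into a DAG
#'
#' @param path TSV with columns `child`, `parent` (extra columns ignored).
#' @return `tf_ontology`: list with `graph` (igraph, edges child -> parent)
#'   and `terms`.
#' @export
read_ontology <- function(path) {
  df <- tf_read_tsv(path, header = TRUE)
  if (ncol(df) < 2) stop("ontology TSV needs columns child, parent", call. = FALSE)
  make_ontology(as.character(df[[1]]), as.character(df[[2]]))
}

#' @rdname read_ontology
#' @param child,parent parallel character vectors of term ids.
#' @export
make_ontology <- function(child, parent) {
  g <- igraph::graph_from_data_frame(data.frame(child, parent), directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle", call. = FALSE)
  structure(list(graph = g, terms = igraph::V(g)$name), class = "tf_ontology")
}

#' Read a bioactivity table
#'
#' @param path TSV with columns `compound_id`, `target_id`, `ki_nM`.
#' @return data.frame of measurements; rows with non-positive or
#'   non-numeric Ki are dropped with a warning.
#' @export
read_bioactivities <- function(path) {
  df <- tf_read_tsv(path, header = TRUE)
  need <- c("compound_id", "target_id", "ki_nM")
  if (!all(need %in% names(df)))
    stop("bioactivity table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ki <- suppressWarnings(as.numeric(df$ki_nM))
  bad <- is.na(ki) | ki <= 0
  if (any(bad))
    warning(sum(bad), " bioactivity row(s) with non-positive or non-numeric ",
            "Ki dropped", call. = FALSE)
  data.frame(compound_id = as.character(df$compound_id)[!bad],
             target_id = as.character(df$target_id)[!bad],
             ki_nM = ki[!bad], stringsAsFactors = FALSE)
}

#' Write a ranked prediction to TSV
#'
#' @param pred data.frame with columns `target_id`, `score` (and optionally
#'   `compound_id`); rows are re-ordered by descending score, ties broken by
#'   target id.
#' @param path output file.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(all(c("target_id", "score") %in% names(pred)))
  if (nrow(pred) && (min(pred$score) < 0 || max(pred$score) > 1))
    stop("scores must be in [0, 1]", call. = FALSE)
  ord <- order(-pred$score, pred$target_id)
  out <- data.frame(rank = seq_len(nrow(pred)),
                    target_id = pred$target_id[ord],
                    score = sprintf("%.6f", pred$score[ord]))
  tf_write_tsv(out, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- tf_read_tsv(path, header = TRUE)
  df$score <- as.numeric(df$score)
  df
}
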