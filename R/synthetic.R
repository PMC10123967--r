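# Download-free synthetic benchmark with the statistical structure the
# method assumes: drug-like compounds from a fragment grammar, a target
# panel with family structure in both sequence and GO annotation, and Ki
# values generated from a planted compound-target compatibility rule
# (fingerprint-bit overlap with a per-target pharmacophore key), centred on
# the 100 nM decision threshold so both classes stay populated at any
# signal strength.

# Fragment grammar: each linker fragment carries a "{}" slot where the rest
# of the molecule is spliced; terminal fragments close the molecule. All
# splices are single bonds, so every assembly is valid by construction.
.tf_linkers <- c(
  "C{}", "CC{}", "CCC{}", "C(C){}", "C(C)C{}", "CO{}", "OC{}", "CN{}",
  "NC{}", "CS{}", "C(=O)N{}", "C(=O)O{}", "C(=O){}", "CC(C){}", "COC{}",
  "CNC{}", "CCN{}", "CCO{}", "C=C{}", "CC=C{}",
  "c1ccc({})cc1", "c1ccc({})nc1", "c1ccc({})cn1", "Cc1ccc({})cc1",
  "c1cc({})ccc1O", "c1cc({})ccc1N", "c1cc({})ccc1F", "c1cc({})ccc1Cl",
  "C1CCN({})CC1", "C1CCC({})CC1", "C1CCN(C{})CC1", "N1CCN({})CC1")
.tf_terminals <- c(
  "C", "CC", "O", "N", "OC", "N(C)C", "C#N", "C(F)(F)F", "Cl", "F",
  "c1ccccc1", "c1ccncc1", "C1CCCCC1", "C(C)(C)C", "C(=O)O", "C(=O)N",
  "S(=O)(=O)N", "OCC", "CO", "NC")

tf_assemble_smiles <- function(linkers, terminal) {
  s <- terminal
  for (f in rev(linkers)) s <- sub("{}", s, f, fixed = TRUE)
  s
}

# A fragment as a standalone molecule (splice slot removed).
tf_fragment_core <- function(frag) {
  s <- gsub("({})", "", frag, fixed = TRUE)
  gsub("{}", "", s, fixed = TRUE)
}

#' Configuration of the synthetic benchmark
#'
#' @param n_targets panel size (>= 10).
#' @param n_compounds library size.
#' @param seed master seed; same seed, same benchmark, byte for byte.
#' @param mean_ligands mean measured ligands per (non-small) target.
#' @param frac_small fraction of targets with <= 5 ligands (exercises the
#'   forced-training rule).
#' @param beta planted signal strength: slope of log10 Ki on the
#'   standardized fingerprint-key overlap (0 = no learnable signal).
#' @param noise_sd Gaussian noise on log10 Ki, in log10 nM units (default
#'   0.5, the order of inter-assay Ki variability).
#' @param family_size targets per sequence/annotation family.
#' @return `tf_synth_config` list.
#' @export
synth_config <- function(n_targets = 60L, n_compounds = 800L, seed = 7L,
                         mean_ligands = 20, frac_small = 0.15, beta = 1.5,
                         noise_sd = 0.5, family_size = 6L) {
  stopifnot(n_targets >= 10, n_compounds > 0, mean_ligands > 0,
            frac_small >= 0, frac_small < 1, beta >= 0, noise_sd >= 0)
  if (mean_ligands > n_compounds)
    stop("more ligands per target requested than compounds exist", call. = FALSE)
  structure(list(n_targets = as.integer(n_targets),
                 n_compounds = as.integer(n_compounds), seed = as.integer(seed),
                 mean_ligands = mean_ligands, frac_small = frac_small,
                 beta = beta, noise_sd = noise_sd,
                 family_size = as.integer(family_size)),
            class = "tf_synth_config")
}

#' Generate the synthetic benchmark
#'
#' @param config a [synth_config()].
#' @return `tf_benchmark`: `compounds` (`tf_compounds`), `panel`
#'   (`tf_panel`), `ontology`, `activities` (measurement table with
#'   replicates), `truth` (planted positive pairs, noise-free), `config`.
#' @export
generate_benchmark <- function(config = synth_config()) {
  set.seed(config$seed)
  ## compounds, remembering which fragments built each one
  nfrag <- sample(2:4, config$n_compounds, replace = TRUE)
  frag_names <- c(.tf_linkers, .tf_terminals)
  comp_frags <- lapply(seq_len(config$n_compounds), function(i)
    c(sample(.tf_linkers, nfrag[i] - 1L, replace = TRUE),
      sample(.tf_terminals, 1L)))
  smiles <- vapply(comp_frags, function(fr)
    tf_assemble_smiles(fr[-length(fr)], fr[length(fr)]), character(1))
  ids <- sprintf("c%04d", seq_len(config$n_compounds))
  compounds <- suppressWarnings(parse_compounds(ids, smiles))
  comp_frags <- comp_frags[match(compounds$ids, ids)]

  ## target panel with family structure
  aa <- .tf_aa
  n_fam <- ceiling(config$n_targets / config$family_size)
  fam_of <- rep(seq_len(n_fam), each = config$family_size)[seq_len(config$n_targets)]
  founders <- lapply(seq_len(n_fam), function(f)
    sample(aa, sample(200:600, 1), replace = TRUE))
  seqs <- vapply(seq_len(config$n_targets), function(t) {
    s <- founders[[fam_of[t]]]
    mut <- sample(length(s), round(0.12 * length(s)))
    s[mut] <- sample(aa, length(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  tids <- sprintf("t%03d", seq_len(config$n_targets))

  ## toy ontology: 3 aspects x 50 terms, random DAG rooted at term 1
  aspects <- c("BP", "MF", "CC")
  edges_child <- character(0); edges_parent <- character(0)
  terms_by_aspect <- list()
  for (a in aspects) {
    terms <- sprintf("%s%03d", a, 1:50)
    terms_by_aspect[[a]] <- terms
    for (i in 2:50) {
      parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
      edges_child <- c(edges_child, rep(terms[i], length(parents)))
      edges_parent <- c(edges_parent, terms[parents])
    }
  }
  ontology <- make_ontology(edges_child, edges_parent)
  fam_terms <- lapply(seq_len(n_fam), function(f)
    lapply(stats::setNames(aspects, aspects), function(a)
      sample(terms_by_aspect[[a]][-1], 4)))
  go_terms <- lapply(seq_len(config$n_targets), function(t)
    lapply(stats::setNames(aspects, aspects), function(a)
      unique(c(fam_terms[[fam_of[t]]][[a]],
               sample(terms_by_aspect[[a]][-1], 2)))))
  panel <- make_panel(tids, seqs, go_terms = go_terms)

  ## planted pharmacophore keys: each target family is anchored on three
  ## signature fragments; the family key is the set of ECFP4 bits those
  ## fragment cores light up, and each member adds the bits of one
  ## member-specific fragment. Compounds carrying a family's signature
  ## chemotype therefore genuinely match its key, others do not.
  fp <- compute_ecfp4(compounds)
  n_sig <- 3L
  pool <- sample(frag_names)
  need <- n_fam * n_sig
  fam_frags <- split(pool[seq_len(min(need, length(pool)))],
                     rep(seq_len(n_fam), length.out = min(need, length(pool))))
  rest <- setdiff(frag_names, unlist(fam_frags))
  if (!length(rest)) rest <- frag_names
  member_frag <- sample(rest, config$n_targets, replace = TRUE)
  frag_bits <- local({
    cores <- unique(tf_fragment_core(frag_names))
    fmols <- suppressWarnings(parse_compounds(
      sprintf("f%02d", seq_along(cores)), cores))
    fbits <- compute_ecfp4(fmols)
    stats::setNames(lapply(seq_len(nrow(fbits)), function(i)
      which(fbits[i, ] == 1L)), fmols$smiles)
  })
  bits_of <- function(frags) {
    cores <- tf_canonical_smiles(tf_fragment_core(frags))
    sort(unique(unlist(frag_bits[cores])))
  }
  target_frags <- lapply(seq_len(config$n_targets), function(t)
    unique(c(fam_frags[[fam_of[t]]], member_frag[t])))
  keys <- lapply(target_frags, bits_of)

  ## activities: log10 Ki = 2 - beta * z + noise, where z is the compound-
  ## key overlap standardized GLOBALLY over all sampled pairs, so that
  ## roughly half of all pairs fall at or below 100 nM while a compound's
  ## strongest targets stay its strongest targets across the panel (the
  ## absolute compatibility structure that target ranking requires)
  ## ligand sampling enriched for compatible chemotypes (half of each
  ## target's measured ligands carry one of its signature fragments),
  ## mirroring the activity-enriched composition of bioactivity databases
  # Tanimoto-style compatibility of every compound with every key:
  # normalizing by the union keeps bit-rich compounds from being potent
  # against every key (selectivity)
  nbits <- rowSums(fp)
  ksizes <- lengths(keys)
  kmat <- matrix(0L, 1024L, config$n_targets)
  for (t in seq_len(config$n_targets)) kmat[keys[[t]], t] <- 1L
  inter_mat <- fp %*% kmat
  omat <- inter_mat / (outer(nbits, ksizes, "+") - inter_mat)
  # a compound's preferred family: the one holding its best-matching target
  fam_score <- vapply(seq_len(n_fam), function(f)
    apply(omat[, fam_of == f, drop = FALSE], 1, max), numeric(nrow(omat)))
  pref_fam <- max.col(fam_score, ties.method = "first")
  n_small <- round(config$frac_small * config$n_targets)
  small <- sample(config$n_targets, n_small)
  pair_t <- integer(0); pair_c <- integer(0)
  for (t in seq_len(config$n_targets)) {
    n_lig <- if (t %in% small) sample(1:5, 1)
             else max(6L, stats::rpois(1, config$mean_ligands))
    n_lig <- min(n_lig, length(compounds$ids))
    # half of the measured ligands are selective chemotypes of this
    # target's family, the rest are arbitrary library members
    compat <- which(pref_fam == fam_of[t] & fam_score[, fam_of[t]] > 0)
    n_c <- stats::rbinom(1, n_lig, 0.5)
    if (!(t %in% small) && length(compat)) n_c <- max(1L, n_c)
    n_c <- min(n_c, length(compat))
    pick_c <- if (n_c) sample(compat, n_c) else integer(0)
    if (!(t %in% small)) {
      # anchor every non-small target with its best-matching library
      # compound, so the planted truth has at least one pair to recover
      best <- sample(which(omat[, t] == max(omat[, t])), 1)
      if (!(best %in% pick_c)) pick_c <- c(best, pick_c)[seq_len(max(1, n_c))]
    }
    others <- setdiff(seq_along(compounds$ids), pick_c)
    pick <- c(pick_c, sample(others, n_lig - length(pick_c)))
    pair_t <- c(pair_t, rep(t, n_lig)); pair_c <- c(pair_c, pick)
  }
  o <- omat[cbind(pair_c, pair_t)]
  o_mu <- mean(o)
  o_sd <- if (stats::sd(o) > 0) stats::sd(o) else 1
  z <- (o - o_mu) / o_sd
  log_ki <- 2 - config$beta * z +
    stats::rnorm(length(z), 0, config$noise_sd)
  activities <- data.frame(compound_id = compounds$ids[pair_c],
                           target_id = tids[pair_t], ki_nM = 10^log_ki,
                           stringsAsFactors = FALSE)
  truth <- list(data.frame(compound_id = compounds$ids[pair_c[z >= 0]],
                           target_id = tids[pair_t[z >= 0]],
                           stringsAsFactors = FALSE))
  ## replicate measurements for ~10% of pairs (small jitter, keeps the
  ## replicate spread well under one order of magnitude)
  nrep <- round(0.1 * nrow(activities))
  if (nrep > 0) {
    idx <- sample(nrow(activities), nrep)
    extra <- activities[idx, , drop = FALSE]
    jitter_sd <- if (config$noise_sd > 0) 0.08 else 0
    extra$ki_nM <- extra$ki_nM * 10^stats::rnorm(nrep, 0, jitter_sd)
    activities <- rbind(activities, extra)
  }
  rownames(activities) <- NULL
  structure(list(compounds = compounds, panel = panel, ontology = ontology,
                 activities = activities,
                 truth = do.call(rbind, truth), config = config,
                 latent = list(fingerprints = fp, keys = keys,
                               target_fragments = target_frags,
                               overlap_mean = o_mu, overlap_sd = o_sd,
                               family = fam_of),
                 ontology_edges = data.frame(child = edges_child,
                                             parent = edges_parent,
                                             stringsAsFactors = FALSE)),
            class = "tf_benchmark")
}

#' Planted positive pairs of a benchmark
#'
#' The noise-free ground truth: pairs whose expected log10 Ki (before the
#' Gaussian draw) is at or below the 100 nM threshold.
#'
#' @param benchmark a `tf_benchmark`.
#' @export
truth_table <- function(benchmark) {
  stopifnot(inherits(benchmark, "tf_benchmark"))
  benchmark$truth
}

#' Write a benchmark to disk in the pipeline's input formats
#'
#' Emits `compounds.tsv`, `proteins.fasta`, `go_annotations.tsv`,
#' `ontology.tsv`, `activities.tsv` under `dir`.
#'
#' @param benchmark a `tf_benchmark`.
#' @param dir output directory (created if missing).
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tf_write_tsv(data.frame(compound_id = benchmark$compounds$ids,
                          smiles = benchmark$compounds$smiles),
               file.path(dir, "compounds.tsv"))
  fa <- Biostrings::AAStringSet(benchmark$panel$sequences)
  names(fa) <- benchmark$panel$ids
  Biostrings::writeXStringSet(fa, file.path(dir, "proteins.fasta"))
  ann <- do.call(rbind, lapply(seq_along(benchmark$panel$ids), function(i) {
    g <- benchmark$panel$go_terms[[i]]
    do.call(rbind, lapply(names(g), function(a)
      if (length(g[[a]])) data.frame(protein_id = benchmark$panel$ids[i],
                                     go_term = g[[a]], aspect = a,
                                     stringsAsFactors = FALSE)))
  }))
  tf_write_tsv(ann, file.path(dir, "go_annotations.tsv"))
  tf_write_tsv(benchmark$ontology_edges, file.path(dir, "ontology.tsv"))
  act <- benchmark$activities
  act$ki_nM <- sprintf("%.6g", act$ki_nM)
  tf_write_tsv(act, file.path(dir, "activities.tsv"))
  invisible(dir)
}

#' @export
print.tf_benchmark <- function(x, ...) {
  cat("<tf_benchmark> ", length(x$compounds$ids), " compounds, ",
      length(x$panel$ids), " targets, ", nrow(x$activities),
      " measurements (beta=", x$config$beta, ", seed=", x$config$seed,
      ")\n", sep = "")
  invisible(x)
}
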