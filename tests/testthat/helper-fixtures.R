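# Shared fixtures, built lazily once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small benchmark used across unit tests: 12 targets (2 families),
# 80 compounds.
fx_bench <- function() fx_get("bench", function()
  generate_benchmark(synth_config(n_targets = 12, n_compounds = 80,
                                  seed = 11, mean_ligands = 14)))

fx_records <- function() fx_get("records", function()
  suppressMessages(label_interactions(aggregate_bioactivities(fx_bench()$activities))))

# Full featurization of the small benchmark (compound blocks, panel blocks,
# six aligned pair-feature sets).
fx_features <- function() fx_get("features", function() {
  b <- fx_bench()
  records <- fx_records()
  cf <- list(ECFP4 = featurize_compounds(b$compounds, "ECFP4"),
             MACCS = featurize_compounds(b$compounds, "MACCS"),
             MOL2D = featurize_compounds(b$compounds, "MOL2D"))
  proa <- compute_proa_panel(b$panel)
  prob <- suppressWarnings(compute_prob_panel(b$panel, b$ontology))
  pf <- list(PROA = proa, PROB = prob)
  schemes <- c("ECFP4-ProA", "ECFP4-ProB", "Mol2D-ProA", "Mol2D-ProB",
               "MACCS-ProA", "MACCS-ProB")
  features <- lapply(setNames(schemes, schemes), function(s) {
    cb <- strsplit(s, "-")[[1]]
    cmp <- toupper(cb[1]); prt <- toupper(cb[2])
    build_pair_features(records, cf[[cmp]], pf[[prt]], s)
  })
  list(records = records, cf = cf, pf = pf, features = features,
       panel_ids = b$panel$ids)
})

# Independent Gotoh (affine-gap) global alignment oracle, Biostrings gap
# convention: a gap of length L costs opening + L * extension.
fx_gotoh_score <- function(s1, s2, sub, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      sub[a[i - 1], b[j - 1]]
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

fx_blosum62 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Brute-force AUC oracle: enumerate all positive-negative pairs.
fx_auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

fx_tsv <- function(df, header = TRUE) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  f
}
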