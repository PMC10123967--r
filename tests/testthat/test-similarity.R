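test_that("sequence similarity is a normalized, symmetric, unit-diagonal matrix", {
  b <- fx_bench()
  S <- fx_features()$pf$PROB$similarities$SEQ
  expect_true(isSymmetric(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= 0 & S <= 1))
  # family structure: within-family similarity beats between-family
  fam <- rep(1:2, each = 6)
  within <- S[outer(fam, fam, "==") & upper.tri(S)]
  between <- S[outer(fam, fam, "!=") & upper.tri(S)]
  expect_gt(mean(within), mean(between))
})

test_that("alignment similarity matches an independent Gotoh implementation", {
  s1 <- "MKTAYIAKQRQISFV"
  s2 <- "MKTAYLAKQRQWSFV"
  s3 <- "GGGGGPPPPPWWWWW"
  panel <- make_panel(c("a", "b", "c"),
                      vapply(c(s1, s2, s3), strrep, "", 2))
  S <- sequence_similarity_matrix(panel)
  B62 <- fx_blosum62()
  sc <- function(x, y) fx_gotoh_score(strrep(x, 2), strrep(y, 2), B62)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    seqs <- c(s1, s2, s3)
    raw <- sc(seqs[pair[1]], seqs[pair[2]])
    self1 <- sum(diag(B62[strsplit(strrep(seqs[pair[1]], 2), "")[[1]],
                          strsplit(strrep(seqs[pair[1]], 2), "")[[1]]]))
    self2 <- sum(diag(B62[strsplit(strrep(seqs[pair[2]], 2), "")[[1]],
                          strsplit(strrep(seqs[pair[2]], 2), "")[[1]]]))
    expected <- min(1, max(0, raw / sqrt(self1 * self2)))
    expect_equal(unname(S[pair[1], pair[2]]), expected, tolerance = 1e-10)
  }
})

test_that("Resnik-BMA similarity matches exhaustive enumeration on a toy DAG", {
  #        root
  #       /    \
  #      A      B
  #     / \      \
  #    C   D      E
  ont <- make_ontology(child = c("A", "B", "C", "D", "E"),
                       parent = c("root", "root", "A", "A", "B"))
  gt <- list(list(BP = c("C", "D"), MF = character(0), CC = character(0)),
             list(BP = "D", MF = character(0), CC = character(0)),
             list(BP = "E", MF = character(0), CC = character(0)))
  panel <- make_panel(c("p1", "p2", "p3"),
                      rep(strrep("ACDEFGHIKL", 4), 3), go_terms = gt)
  S <- go_similarity_matrix(panel, ont, "BP")
  # corpus: C,D,D,E -> 4 annotations in BP
  # p(C)=1/4, p(D)=2/4, p(E)=1/4, p(A)=3/4 (C,D desc), p(B)=1/4, p(root)=1
  ic <- c(C = -log(1/4), D = -log(2/4), E = -log(1/4),
          A = -log(3/4), B = -log(1/4), root = 0)
  maxic <- max(ic)
  anc <- list(C = c("C", "A", "root"), D = c("D", "A", "root"),
              E = c("E", "B", "root"))
  tsim <- function(t1, t2) {
    common <- intersect(anc[[t1]], anc[[t2]])
    max(ic[common]) / maxic
  }
  bma <- function(T1, T2) {
    m <- outer(T1, T2, Vectorize(tsim))
    (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (length(T1) + length(T2))
  }
  expect_equal(unname(S[1, 2]), bma(c("C", "D"), "D"), tolerance = 1e-12)
  expect_equal(unname(S[1, 3]), bma(c("C", "D"), "E"), tolerance = 1e-12)
  expect_equal(unname(S[2, 3]), bma("D", "E"), tolerance = 1e-12)
  expect_equal(unname(diag(S)), rep(1, 3))
})

test_that("proteins whose only shared ancestor is the root have similarity 0", {
  ont <- make_ontology(child = c("A", "B"), parent = c("root", "root"))
  gt <- list(list(BP = "A", MF = character(0), CC = character(0)),
             list(BP = "B", MF = character(0), CC = character(0)))
  panel <- make_panel(c("p1", "p2"), rep(strrep("ACDEFGHIKL", 4), 2),
                      go_terms = gt)
  S <- go_similarity_matrix(panel, ont, "BP")
  expect_equal(unname(S[1, 2]), 0)
  expect_equal(unname(diag(S)), c(1, 1))
})

test_that("empty aspects give identity matrices with a warning", {
  ont <- make_ontology("A", "root")
  panel <- make_panel(c("p1", "p2"), rep(strrep("ACDEFGHIKL", 4), 2))
  expect_warning(S <- go_similarity_matrix(panel, ont, "CC"), "identity")
  expect_equal(S, diag(2), ignore_attr = TRUE)
})

test_that("ProB dimensionality follows the rank bound 4 x min(50, N-1)", {
  prob <- fx_features()$pf$PROB
  expect_equal(ncol(prob$features), 4 * (12 - 1))
  expect_true(all(is.finite(prob$features)))
})
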