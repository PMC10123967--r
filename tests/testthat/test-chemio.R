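test_that("SMILES tables parse, rejects are logged, duplicate ids are fatal", {
  f <- fx_tsv(data.frame(compound_id = c("c1", "c2", "c3"),
                         smiles = c("CCO", "not_a_smiles", "c1ccccc1")))
  expect_warning(cp <- read_compounds(f), "failed")
  expect_equal(cp$ids, c("c1", "c3"))
  expect_equal(cp$mols[[1]]$n_heavy, 3)  # ethanol: C, C, O

  fdup <- fx_tsv(data.frame(compound_id = c("a", "a"),
                            smiles = c("CCO", "CCN")))
  expect_error(read_compounds(fdup), "duplicate")
  expect_error(read_compounds(tempfile()), "not found")
  fbad <- fx_tsv(data.frame(compound_id = "x", smiles = "zzz"))
  expect_error(suppressWarnings(read_compounds(fbad)), "zero compounds")
})

test_that("SDF input is accepted through the OpenBabel conversion path", {
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", "CCO mol_a\nc1ccccc1 mol_b\n")
  f <- tempfile(fileext = ".sdf")
  writeLines(sdf, f)
  cp <- read_compounds(f, format = "sdf")
  expect_equal(cp$ids, c("mol_a", "mol_b"))
  expect_equal(cp$mols[[2]]$n_heavy, 6)
})

test_that("different spellings of one molecule share a canonical structure", {
  cp <- parse_compounds(c("a", "b", "c"),
                        c("OCC", "CCO", "C(O)C"))
  expect_equal(cp$smiles[1], cp$smiles[2])
  expect_equal(cp$smiles[1], cp$smiles[3])
})

test_that("salt stripping keeps the largest fragment", {
  cp <- parse_compounds("s1", "CC(=O)O.[Na]")
  expect_equal(cp$mols[[1]]$n_heavy, 4)  # acetate, sodium dropped
})

test_that("target panels read FASTA + annotations; ontology cycles are fatal", {
  seqs <- c(p1 = paste(rep("ACDEFGHIKL", 5), collapse = ""),
            p2 = paste(rep("MNPQRSTVWY", 5), collapse = ""))
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  ann_empty <- fx_tsv(data.frame(protein_id = character(0),
                                 go_term = character(0),
                                 aspect = character(0)))
  ont <- fx_tsv(data.frame(child = c("B", "C"), parent = c("A", "A")))
  tp <- read_target_panel(fa, ann_empty, ont)
  expect_length(tp$panel$ids, 2)
  expect_true(all(lengths(tp$panel$go_terms[[1]]) == 0))

  ann_unknown <- fx_tsv(data.frame(protein_id = "pX", go_term = "B",
                                   aspect = "BP"))
  expect_warning(tp2 <- read_target_panel(fa, ann_unknown, ont), "absent")
  expect_true(all(lengths(tp2$panel$go_terms[[1]]) == 0))

  cyc <- fx_tsv(data.frame(child = c("A", "B"), parent = c("B", "A")))
  expect_error(read_target_panel(fa, ann_empty, cyc), "cycle")

  ann_ok <- fx_tsv(data.frame(protein_id = c("p1", "p1"), go_term = c("B", "C"),
                              aspect = c("BP", "MF")))
  tp3 <- read_target_panel(fa, ann_ok, ont)
  expect_equal(tp3$panel$go_terms[[1]]$BP, "B")
  expect_equal(tp3$panel$go_terms[[1]]$MF, "C")
})

test_that("bioactivity reading drops bad Ki rows and demands its columns", {
  f <- fx_tsv(data.frame(compound_id = c("c1", "c1", "c1"),
                         target_id = c("t1", "t1", "t1"),
                         ki_nM = c("50", "-3", "abc")))
  expect_warning(df <- read_bioactivities(f), "dropped")
  expect_equal(nrow(df), 1)
  expect_equal(df$ki_nM, 50)
  fmiss <- fx_tsv(data.frame(compound_id = "c1", target_id = "t1"))
  expect_error(read_bioactivities(fmiss), "columns")
})

test_that("prediction TSV round-trips ranks and 6-decimal scores", {
  pred <- data.frame(target_id = c("t2", "t1", "t3"),
                     score = c(0.5, 0.9, 0.1))
  f <- tempfile(fileext = ".tsv")
  write_predictions(pred, f)
  back <- read_predictions(f)
  expect_equal(back$rank, 1:3)
  expect_equal(back$target_id, c("t1", "t2", "t3"))  # descending by score
  expect_equal(back$score, c(0.9, 0.5, 0.1), tolerance = 1e-7)

  f2 <- tempfile(fileext = ".tsv")
  write_predictions(pred[0, ], f2)
  expect_equal(nrow(read_predictions(f2)), 0)  # header-only

  expect_error(write_predictions(data.frame(target_id = "t", score = 1.2), f),
               "\\[0, 1\\]")
})
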