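test_that("fingerprint blocks have the contracted lengths and are binary", {
  cp <- parse_compounds(c("a", "b"), c("CCO", "CC(=O)Oc1ccccc1C(=O)O"))
  fp <- compute_ecfp4(cp)
  mk <- compute_maccs(cp)
  expect_equal(dim(fp), c(2L, 1024L))
  expect_equal(dim(mk), c(2L, 166L))
  expect_true(all(fp %in% 0:1))
  expect_true(all(mk %in% 0:1))
})

test_that("benzene ECFP4 matches the reference circular-fingerprint bit count", {
  # frozen oracle: RDKit Morgan radius-2/1024-bit fingerprint of benzene
  # sets exactly 3 bits (one environment per iteration 0..2)
  fp <- compute_ecfp4(parse_compounds("bz", "c1ccccc1"))
  expect_equal(sum(fp), 3)
})

test_that("methane fires at most 3 MACCS keys", {
  mk <- compute_maccs(parse_compounds("m", "C"))
  expect_lte(sum(mk), 3)
})

test_that("descriptors are invariant to SMILES spelling and atom order", {
  spellings <- c("CC(=O)Oc1ccccc1C(=O)O",      # aspirin, three atom orders
                 "O=C(C)Oc1ccccc1C(O)=O",
                 "OC(=O)c1ccccc1OC(C)=O")
  cp <- parse_compounds(c("s1", "s2", "s3"), spellings)
  fp <- compute_ecfp4(cp); mk <- compute_maccs(cp)
  m2 <- compute_mol2d_matrix(cp)
  for (i in 2:3) {
    expect_equal(unname(fp[1, ]), unname(fp[i, ]))
    expect_equal(unname(mk[1, ]), unname(mk[i, ]))
    expect_equal(unname(m2[1, ]), unname(m2[i, ]), tolerance = 1e-12)
  }
})

test_that("Mol2D has 188 finite descriptors in the documented families", {
  man <- mol2d_manifest()
  expect_equal(nrow(man), 188)
  shipped <- jsonlite::read_json(
    system.file("extdata", "mol2d_manifest.json", package = "targetfisher"),
    simplifyVector = TRUE)
  expect_identical(shipped$name, man$name)
  expect_equal(as.vector(table(man$family)[c("constitutional", "topological",
                                             "connectivity", "kappa", "basak",
                                             "charge", "moe")]),
               c(30, 25, 44, 7, 21, 25, 36))
  cp <- parse_compounds("a", "CC(=O)Oc1ccccc1C(=O)O")
  v <- compute_mol2d(cp$mols[[1]])
  expect_length(v, 188)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), man$name)
})

test_that("hand-computable Mol2D values are exact", {
  ethanol <- parse_compounds("e", "CCO")$mols[[1]]
  propane <- parse_compounds("p", "CCC")$mols[[1]]
  ve <- compute_mol2d(ethanol); vp <- compute_mol2d(propane)
  expect_equal(ve[["natom"]], 3)
  # Randic index on the 3-vertex path: 2 * (1*2)^(-1/2)
  expect_equal(vp[["chi1p"]], 2 / sqrt(2), tolerance = 1e-9)
  # Wiener number of the path graph P3: 1 + 1 + 2
  expect_equal(vp[["wiener"]], 4)
  expect_equal(vp[["nC"]], 3)
  expect_equal(ve[["nHBD"]], 1)   # hydroxyl
  expect_equal(ve[["nHBA"]], 1)
  # benzene: 6 aromatic atoms, one ring, kappa1 == A(A-1)^2/P1^2 = 6*25/36
  bz <- compute_mol2d(parse_compounds("b", "c1ccccc1")$mols[[1]])
  expect_equal(bz[["naromatom"]], 6)
  expect_equal(bz[["nring"]], 1)
  expect_equal(bz[["kappa1"]], 6 * 25 / 36, tolerance = 1e-9)
})

test_that("featurization is deterministic and preserves row order", {
  cp <- fx_bench()$compounds[1:5]
  a <- featurize_compounds(cp, "ECFP4")
  b <- featurize_compounds(cp, "ECFP4")
  expect_identical(a, b)
  expect_equal(dim(a), c(5L, 1024L))
  expect_equal(rownames(a), cp$ids)
})
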