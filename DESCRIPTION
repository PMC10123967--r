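Package: targetfisher
Title: Ensemble Chemogenomic Target Prediction from Multi-Scale Compound
    and Protein Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemogenomic prediction of compound-target interactions and
    ranking of a fixed protein target panel for query compounds. Each
    compound-target pair is represented by the concatenation of a compound
    descriptor block (ECFP4 circular fingerprint, MACCS keys, or a
    188-descriptor 2D suite) and a protein descriptor block (762
    physicochemical sequence descriptors or 200 similarity-matrix-derived
    descriptors built from BLOSUM62 alignment and Resnik GO semantic
    similarity). Six gradient-boosted-tree classifiers, one per descriptor
    combination, are fused by mean, maximum, or stacked averaging and used
    to rank the panel for target fishing. Includes the full evaluation
    protocol (stratified pair-split and compound-split 10-fold
    cross-validation, ACC/SE/SP/AUC, recall at k, enrichment folds) and a
    download-free synthetic benchmark generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Biostrings,
    igraph,
    xgboost,
    Matrix,
    jsonlite,
    optparse,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
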