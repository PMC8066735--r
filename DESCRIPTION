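Package: plantloc
Title: Heterogeneous Ensemble Prediction of Plant Protein Subcellular
    Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the subcellular localization of plant proteins among
    11 compartments, allowing single- and dual-compartment calls. Encodes
    each protein as a 479-dimensional feature vector (amino acid
    composition, four pseudo amino acid composition variants,
    composition-transition-distribution descriptors, Geary autocorrelation,
    quasi-sequence-order descriptors, physicochemical indices and property
    scale projections, external sorting-signal predictor scores, and a
    GO-homology feature), reduces it with ReliefF, OneR or correlation-based
    feature selection with a genetic search, and classifies with an average
    voting ensemble of inverse-distance-weighted k-nearest neighbours,
    random forest and gradient boosted trees. Includes stratified
    cross-validation, one-vs-rest performance metrics, a per-compartment
    Pearson feature analysis, and a seeded synthetic-data generator for
    end-to-end testing without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    seqinr,
    stats,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
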