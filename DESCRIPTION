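Package: deamidate
Title: Structure-Based Prediction of Asparagine Deamidation Liability
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts which asparagine residues in a protein structure are
    liable to spontaneous deamidation. Reads X-ray structures in PDB format,
    enumerates candidate Asn sites, and computes a 13-descriptor feature set
    combining an experimentally measured penta-peptide deamidation half-life
    with structure-derived properties (backbone and side-chain dihedrals,
    normalized crystallographic B-factors, percent solvent accessibility,
    local secondary structure, and the nucleophilic attack C-N distance).
    Trains and cross-validates six classifier families (random forest,
    RBF-kernel SVM, naive Bayes, k-nearest-neighbour, single-hidden-layer
    neural network, and PLS discriminant analysis), ranks descriptors by
    recursive feature elimination, and evaluates predictions with an
    unbalanced-data metric suite (confusion matrix, recall, specificity,
    precision, MCC, ROC/AUC) including an NG-motif sequence baseline.
    Includes a deterministic synthetic-data module that builds peptide
    structures from internal coordinates and feature tables with planted
    signal for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    quadprog,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
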