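Package: confcascade
Title: Two-Stage Imbalance-Aware Prediction of Ligand-Binding Protein
    Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which apo-protein conformations from molecular-dynamics
    ensembles are "binding" conformations (conformational selection) from
    tables of per-frame physico-chemical descriptors. Provides consensus
    feature selection over four scorers (one-way ANOVA F, mutual information,
    recurrence quantification entropy, Spearman correlation), a two-stage
    class-imbalance-aware classification cascade (gradient-boosted trees,
    then GAN minority oversampling plus K-Means majority undersampling
    feeding small convolutional and recurrent neural classifiers), and an
    enrichment-ratio framework for evaluating predicted binding conformations
    against random selection. Includes a synthetic-data generator that
    emulates the class-imbalanced, serially autocorrelated structure of
    MD descriptor tables, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
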