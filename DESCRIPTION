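Package: snvmeta
Title: Ensemble Meta-Prediction of Disease-Associated Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the raw scores of four heterogeneous missense-variant
    predictors (PANTHER, PhD-SNP, SIFT, SNAP) with sequence-profile features
    (wild-type and mutant residue frequencies, alignment depth and a
    conservation index) into a random-forest meta-classifier of
    disease-associated versus polymorphic protein variants. Provides
    threshold-based score interpretation with missing-score imputation,
    stratified cross-validation with out-of-fold probabilities and a
    reliability index, consensus/majority/tie predictor-agreement
    stratification, pairwise method-similarity analysis with UPGMA trees,
    full performance metrics (accuracy, predictive values, Matthews
    correlation, ROC/AUC), a synthetic benchmark generator, and a
    command-line interface over the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    randomForest,
    ape,
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
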