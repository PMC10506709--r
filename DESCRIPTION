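Package: hotspotcnn
Title: Protein Hot-Spot Residue Prediction with Sequence Embeddings and a 1-D CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interaction hot-spot residues from
    sequence alone. Residues are labelled from alanine-scanning binding
    free-energy changes (hot spot if ddG > 2 kcal/mol), featurized per
    residue by one-hot encoding and/or precomputed protein language-model
    embeddings, cut into zero-padded sliding windows centered on annotated
    residues, rebalanced by interval undersampling of the majority class
    plus SMOTE oversampling of the minority class (or inverse-frequency
    class weights), and classified by a three-layer one-dimensional
    convolutional neural network trained with RMSprop and early stopping
    on validation F1. Includes confusion-matrix metrics and ROC/AUC
    evaluation, a synthetic motif-planted data generator for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
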