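Package: phoscnn
Title: Leukemia-Related Phosphorylation-Site Prediction from Primary Sequence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease-associated phosphorylation sites (Ser/Thr/Tyr)
    from protein primary sequence alone. Builds balanced, redundancy-reduced
    peptide-window datasets from FASTA sequences and site annotation tables,
    trains a compact convolutional neural network (one convolution, one
    max-pooling and one hidden dense layer) on one-hot encoded windows,
    supports shared-parameter transfer learning to small datasets, and
    benchmarks against five classical machine-learning methods on ordinal
    encodings. Includes K-means cluster-stratified validation, 10-fold and
    leave-one-out cross-validation, confusion-matrix metrics and ROC/AUC,
    position-specific residue enrichment profiles, and motif extraction from
    convolution-filter activations. A synthetic proteome generator with
    planted phospho-motifs and latent sample clusters makes the whole
    pipeline testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    Matrix,
    stats,
    utils,
    methods,
    e1071,
    randomForest,
    xgboost,
    class,
    jsonlite,
    generics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
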