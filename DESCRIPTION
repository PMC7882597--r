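Package: bowdti
Title: Bag-of-Words Sequence Features and Gradient Boosting for
    GPCR-Drug Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts interactions between G protein-coupled receptors
    (GPCRs) and drug molecules from sequence and fingerprint data alone.
    Protein sequences are encoded with the Kyte-Doolittle hydropathy scale
    and represented by a bag-of-words model whose wordbooks are learned by
    K-means clustering of sequence fragments, with the number of words
    selected by a weighted silhouette coefficient.  Drug molecular
    fingerprints (hexadecimal FP2-style strings) are converted to feature
    vectors by a single-level Haar wavelet transform (or discrete Fourier
    transform).  Pair feature vectors are balanced with SMOTE, optionally
    compressed by a small feed-forward neural network, and classified with
    gradient boosted trees (with random forest, RBF-SVM and logistic
    regression comparators).  Includes a cross-validation and metrics
    harness, a synthetic benchmark generator, and file-format readers and
    writers for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    xgboost,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
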