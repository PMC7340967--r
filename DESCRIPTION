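Package: rnam5c
Title: Sequence-Feature Models for RNA 5-Methylcytosine Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature encoders and classifier workflows for predicting RNA
    5-methylcytosine (m5C) sites from fixed-length cytosine-centered
    sequence windows. Implements position-specific mono-, di- and
    tri-nucleotide propensity encodings fitted on labeled training data,
    k-mer and windowed nucleotide compositions, gapped k-mer families,
    electron-ion interaction pseudopotential encodings, parallel-correlation
    pseudo-dinucleotide composition, one-hot and chemical-property
    encodings; a feature-fusion registry with named presets of verified
    dimensionality; SVM, random-forest, AdaBoost and Gaussian naive-Bayes
    backends with stratified k-fold cross-validation, sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC evaluation, and
    hyperparameter grid search. A synthetic-window generator plants
    class-dependent position-specific nucleotide enrichment so the full
    train/evaluate loop is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
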