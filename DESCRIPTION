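Package: cholecon
Title: Consensus Ensemble Models for Drug-Induced Cholestasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds binary chemical and biological fingerprint matrices
    (compound-target bioactivity, interactome-expanded pathway membership,
    substructure keys, hepatic transporter inhibition votes), handles the
    strong class imbalance of public cholestasis data by 4-subset
    undersampling and SMOTE, and combines tree-based base learners into
    vote-rule consensus classifiers (4-submodel undersampling consensus and
    a 9-model expanded consensus) with probability-range confidence
    filtering. Includes the full evaluation machinery: Matthews correlation
    coefficient and balanced-accuracy metrics, probability-band tabulation,
    pooled stratified 10-fold cross-validation, balanced-accuracy model
    selection, mean-scaled feature-importance aggregation, and a seeded
    synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
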