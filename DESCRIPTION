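Package: malopred
Title: Hybrid Convolutional and Ensemble Models for Lysine Malonylation
    Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts lysine malonylation (Kmal) sites in mammalian and
    plant proteins from primary sequence. Proteins are segmented into
    fixed-length lysine-centered peptide fragments which are featurised
    five ways (amino-acid composition, one-hot, pseudo-amino-acid
    composition, physicochemical property matrices with information-gain
    property selection, and position-specific scoring matrix profiles).
    Per-feature base learners (a compact convolutional network for matrix
    features, random forests for vector features) are stacked by a
    neural-network meta-learner (mammalian preset) or an RBF support
    vector machine (plant preset), with published decision cutoffs.
    Includes evaluation metrics (sensitivity, specificity, accuracy,
    Matthews correlation coefficient, ROC-AUC), descriptive sequence
    statistics (class-wise composition, two-sample-logo-style positional
    enrichment, feature-label correlation screening), and a synthetic
    proteome generator so the full pipeline is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    randomForest,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
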