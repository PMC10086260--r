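Package: eigenCoord
Title: Eigen-Spectrum Coordination Analysis of Gene Sets with a
    Soft-Voting Ensemble Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the coordination of a small gene set between two
    sample groups through the normalized eigenvalue spectrum of the
    inner-product (Gram) matrix of Z-scored expression rows: a dominant
    leading eigenvalue indicates tightly co-varying genes, a flat
    spectrum indicates independence.  Provides the supporting stages of
    a hub-gene biomarker workflow: a block-correlated multivariate
    normal expression simulator, two-group differential-expression
    filtering with Benjamini-Hochberg adjustment, confidence-filtered
    protein-protein interaction degree ranking, and a weighted
    soft-voting ensemble classifier evaluated with from-scratch ROC and
    AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
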