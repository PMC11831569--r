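Package: fibrosen
Title: Fibroblast Senescence Signatures for Tumor Immunology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies fibroblast senescence-associated gene
    signatures from single-cell and bulk tumor transcriptomes. Provides
    per-cell gene-set enrichment scoring via a Kolmogorov-Smirnov random
    walk, cross-dataset signature aggregation by geometric-mean Spearman
    correlation, bulk-cohort scoring with signature-by-mutation-burden
    stratification, an immunotherapy-response classifier harness, a
    multi-task logistic regression survival model with differential
    expression feature selection, CRISPR-screen z-score integration for
    target nomination, and a seeded synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    survival,
    xgboost,
    fgsea,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
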