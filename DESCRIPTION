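Package: conncpm
Title: Directional Connectome-Based Predictive Modeling for Case-Control Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) with a linear
    support-vector classifier for case-control studies of functional
    connectivity. From node time series or precomputed Fisher-z connectivity
    matrices, edges associated with diagnosis are selected by point-biserial
    correlation, split by direction (increased versus decreased in patients),
    summed into one or two predictive scores, and classified with a
    soft-margin linear model. Model assessment covers leave-one-out and
    stratified k-fold cross-validation, cross-cohort transfer, p-threshold
    search, label-permutation null distributions, exact sign tests, consensus
    edges across folds, and network-pair edge-count summaries. A synthetic
    cohort generator plants bidirectional edge effects in single- and
    two-site designs so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
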