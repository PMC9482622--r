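Package: shapboost
Title: Explainable Gradient Tree Boosting for Family-Structured Cohort Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates family-structured cohort data with ordinal
    substance-use outcomes driven by a latent liability model with planted
    main and sex-interaction effects; derives brain-connectivity features
    (nodal global and local efficiency on proportionally thresholded graphs,
    within- and between-network connectivity, effect-size-thresholded
    activation clusters); fits second-order gradient tree boosting
    classifiers with sparsity-aware missing-value routing, subsampling and
    early stopping; computes exact and fast Shapley attributions and
    pairwise Shapley interaction values on the fitted tree ensembles; and
    aggregates factor importance across family-blocked nested
    cross-validation models via normalized importances, cross-model median
    ranks and a sex-interaction report with effect-size bins.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
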