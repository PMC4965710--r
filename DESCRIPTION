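Package: tempoRF
Title: Temporal Weighting of Clinical Events for Adverse Drug Event
    Detection with Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns temporal weights of time-stamped clinical events in
    longitudinal electronic health records from random-forest Gini variable
    importance, and applies them either by weighted aggregation of
    time-binned event counts or by weighted candidate-feature sampling
    inside the forest (an enriched random forest). Ships a from-scratch
    Gini-split forest with per-node weighted feature-subspace sampling and
    tree-versus-ensemble error decomposition, a synthetic longitudinal
    cohort generator with planted window-specific signal, and an evaluation
    harness with stratified cross-validation, exact Wilcoxon signed-rank,
    Friedman and Bergmann-Hommel post-hoc statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
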