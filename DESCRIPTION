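Package: loscade
Title: Cascade Generalization Ensembles for Hospital Length-of-Stay Prediction
Version: 0.1.0
Authors@R:
    person("LOS", "Maintainers", email = "maintainers@loscade.org", role = c("aut", "cre"))
Description: Predicts hospital length of stay (LOS) for cardiac inpatients from
    tabular electronic health record data. Provides a synthetic multi-table
    cohort generator with planted effects, the full clinical feature-engineering
    pipeline (admission history, surgery recency, vital-sign range flags, lab
    aggregation), statistical preprocessing (log transform, IQR winsorization,
    min-max scaling, dummy encoding, quantile target binning), univariate
    feature-subset selection (Pearson, Kruskal-Wallis, chi-square), four
    ensemble architectures that fuse a LOS-category classifier with regressors
    (average voting, two- and three-level sequential cascades, and a parallel
    cascade), and a leakage-guarded five-fold nested cross-validation harness
    with randomized hyperparameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
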