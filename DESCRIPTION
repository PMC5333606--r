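Package: parenclitic
Title: Patient-Specific Parenclitic Deviation Networks for Survival Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds patient-specific "parenclitic" networks from tabular
    clinical cohorts: pairwise linear baselines are fitted on a reference
    (surviving) population, each subject's deviations from those baselines
    become residual Z-score edge weights, and the resulting graphs are
    reduced to two topological features (link density and information
    content) that can be fed to a linear support vector machine alongside
    the raw features. Includes a synthetic cohort generator with planted
    pairwise deviations, a leakage-controlled cross-validation harness with
    per-fold baseline recomputation, greedy forward feature selection, and
    plotting and tidying methods for all result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
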