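Package: grpstack
Title: Stacked Ensembles of Group-Penalized Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coordinate-descent solvers for penalized linear regression with
    grouped predictors (group lasso, group SCAD, group MCP, and L0 group
    subset selection with optional group-lasso or ridge shrinkage), together
    with scalar penalties (lasso, SCAD, MCP, elastic net, adaptive lasso),
    cross-validated tuning over warm-started regularization paths, and a
    stacked-generalization ensemble ("StackingGroup") that combines several
    group-penalized base learners through out-of-fold predictions and a lasso
    meta-learner. Includes a synthetic-data generator for group-structured
    designs, a simulation benchmark harness, prediction metrics, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
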