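Package: whackanode
Title: Case-Control Simulation of Functional Connectome Thresholding Artifacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo simulation of case-control resting-state functional
    connectivity studies built on a multilevel model of between-person,
    within-person, and node-targeted variation around a fixed groundtruth
    correlation matrix. Implements proportional (density), absolute
    (correlation-value), and weighted edge-definition strategies, nodal graph
    metrics (degree, strength, within/between-module degree), small-worldness
    against degree-preserving rewired null ensembles, and the group-difference
    inference layer (nodewise two-sample t tests, density-covaried tests,
    multilevel regression across thresholds) needed to demonstrate how
    proportional thresholding induces spurious nodal group differences
    ("whack-a-node") while global small-worldness stays insensitive to large
    modular reorganization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
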