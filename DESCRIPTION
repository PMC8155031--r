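Package: gclsim
Title: Global Coordination Level Statistic and Regulatory-Network Cohort
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measures system-wide gene-to-gene coordination in expression
    cohorts with the global coordination level (GCL): the bias-corrected
    distance correlation between two random complementary halves of the
    gene set, averaged over many random splits. Includes a gene regulatory
    network (GRN) steady-state simulator with tunable regulatory
    heterogeneity and multiplicative measurement noise, cell-to-cell
    variability and average co-expression metrics, a compositional null
    model for spurious-correlation studies, cell-level quality filters,
    and orchestration of the parameter-sweep simulation studies that
    contrast biological with technical cell-to-cell variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    pracma,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
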