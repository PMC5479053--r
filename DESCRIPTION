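Package: reporterfidelity
Title: Fidelity of Fluorescent Reporters Under Feedback Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative assessment of how genetic fluorescent reporters
    represent -- and perturb -- the expression of the genes they monitor,
    motivated by Nanog reporters in embryonic stem cells. Provides closed-form
    joint distributions and exact samplers for the mRNA output of two alleles
    sharing a fluctuating upstream regulator (Gamma-Poisson mixtures and the
    bivariate negative binomial), a Gillespie simulator for bursty two-state
    transcription, equilibrium and saddle-node bifurcation analysis of a
    Hill-type positive-feedback circuit with reporter-design-induced rescaling
    of the dimensionless feedback strength, and a flow-cytometry statistics
    pipeline: MESF bead calibration, percentile alignment, Gaussian-mixture
    fitting with BIC model selection and bimodality criteria, and James-Stein
    shrinkage estimation of mutual information over Bayesian-blocks
    discretization. Seeded synthetic-data generators emulate bimodal and
    unimodal two-channel cell populations and differentiation time-courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
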