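Package: mchbench
Title: Subnational Benchmarking of Maternal and Child Health Coverage and Under-5 Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking maternal and child health (MCH) system
    performance across subnational regions from sparse multi-source survey
    data. Implements design-weighted indicator estimation with
    Taylor-linearized variances, direct under-5 mortality (5q0) from
    complete birth histories via synthetic-cohort life tables, a two-stage
    coverage smoother (natural-cubic-spline mixed model feeding a Gaussian
    process regression with Matern covariance), a Bayesian hierarchical
    spatiotemporal model for logit under-5 mortality with conditional
    autoregressive and random-walk priors fit by Gibbs sampling, and an
    equal-weight 11-indicator overall intervention coverage index. Ships a
    full synthetic-data generator emulating the multi-source survey
    structure of a 10-region, 1990-2011 study design so that every stage
    is testable end to end without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    stats,
    splines,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
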