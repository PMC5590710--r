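Package: mlmmpower
Title: Power Analysis for Multi-Endpoint Longitudinal Trials via
    Multivariate Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and power analysis for two-arm longitudinal clinical
    trials with several correlated outcomes, motivated by cognitive
    endpoints in early Alzheimer's disease. Component scores are modelled
    jointly by a multivariate linear mixed-effects model with correlated
    random intercepts and correlated within-visit errors. The package
    computes the covariance of the treatment-by-time effect estimator from
    the trial design, derives noncentral chi-square power for three Wald
    tests (the joint test of all component effects, the test of a weighted
    combination of effects, and the test based on a univariate model for a
    weighted composite score), solves for required sample sizes, derives
    optimal composite weights, verifies analytic power by Monte-Carlo
    simulation, and fits the multivariate model to longitudinal data by an
    EM algorithm so that estimated parameters feed directly back into the
    power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
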