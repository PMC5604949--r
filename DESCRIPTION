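Package: hilbo
Title: Human-in-the-Loop Bayesian Optimization of Gait Parameters from
    Breath-by-Breath Metabolic Cost
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing a gait parameter (walking step frequency)
    online against noisy, slowly-responding metabolic cost measured by
    indirect calorimetry. Implements breath-by-breath conversion of gas
    exchange to metabolic power (Brockway equation), estimation of the
    instantaneous energetic cost by inverting a first-order model of the
    respiratory response, Gaussian-process regression over step frequency
    with marginal-likelihood hyperparameter fitting, expected-improvement
    Bayesian optimization, a finite-difference gradient-descent comparator,
    post-hoc convergence and energy-expenditure analyses against a
    grid-search landscape baseline, and a fully synthetic treadmill subject
    for end-to-end simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
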