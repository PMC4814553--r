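Package: bistabledcm
Title: Dynamic Causal Modeling of Top-Down Control in Bistable Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying age-dependent effective
    connectivity during bistable perception with dynamic causal modeling
    (DCM) for fMRI. Implements percept-duration and bias-ratio statistics
    from button-press streams, general-linear-model regressor construction
    with a canonical hemodynamic response function, F-contrasts,
    effects-of-interest adjustment and principal-eigenvariate extraction
    for regions of interest, a bilinear neuronal state equation coupled to
    balloon-Windkessel hemodynamics with stochastic neuronal innovations,
    variational-Laplace model inversion, and fixed- and random-effects
    Bayesian model selection with Dirichlet exceedance probabilities.
    Includes a synthetic-cohort generator so the full pipeline runs with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix
Config/testthat/edition: 3
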