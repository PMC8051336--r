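Package: ecoevolve
Title: Punctuated Evolutionary Dynamics of a Self-Developing Ecosystem Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a three-variable model of the
    evolutionary self-development of a large ecosystem: biota density under
    logistic reproduction with density-dependent mortality, coupled to an
    evolving carrying capacity and an evolving mortality coefficient whose
    rates are given by recursively defined power series in the inverse
    carrying capacity. Provides closed-form evaluation of all model laws and
    their partial derivatives, adaptive (optimal) truncation of the
    asymptotic evolution series, stiffness-aware numerical integration,
    equilibrium and bistability analysis of the frozen density equation with
    saddle-node event detection, classification of long-run dynamical
    regimes (stationary, periodic, chaotic) including Lyapunov-exponent
    estimation, segmentation of punctuated cycles into collapse, low-density,
    explosive-growth and stasis phases, and calibration of the base rate
    constants from published equilibrium triples by deterministic multistart
    least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
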