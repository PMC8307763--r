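Package: sfekinetics
Title: Supercritical Fluid Extraction Kinetics Modelling and Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling packed-bed supercritical CO2 extraction of
    seed oils. Implements five empirical yield-curve models
    (pseudo-first-order, corrected exponential, hyperbolic, two-pool
    exponential and a piecewise constant-rate model), a numerical
    two-phase mass-balance model of the extraction bed with a
    time-switched global mass-transfer coefficient, and two piecewise
    analytical solutions of Sovova's broken-and-intact-cells model in the
    solvent-consumption coordinate. Provides nonlinear least-squares
    fitting with multi-start initialisation, goodness-of-fit scoring
    (SSE, R2, AARD), initial-slope estimation, one-factor-at-a-time
    effect summaries, a Box-Behnken design and synthetic kinetic-curve
    generator, and a small feed-forward network surrogate of the initial
    slope with Yoon weight-based sensitivity analysis and grid
    optimization of operating conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
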