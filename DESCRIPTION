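Package: diffsens
Title: Differential Sensitivity Analysis for Dynamical Models in Biology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derivative engines (complex-step first and second order
    including mixed partials, forward and central finite differences, and a
    minimal dual-number forward mode) applied to sensitivity analysis of
    biological dynamical systems. Includes forward sensitivity equations and
    continuous adjoint gradients for ordinary differential equation models
    (tumour-immune CARRGO, deterministic SIR, the stiff Robertson system),
    first- and second-order Taylor prediction of perturbed trajectories,
    first-step-analysis recurrences for the stochastic SIR chain (mean
    extinction time and mean total infected) with complex-step and manual
    tandem sensitivities plus an exact Gillespie simulator, and
    birth-death-migration branching processes (growth rate, extinction
    probabilities, total progeny) with analytic sensitivities cross-checked
    by complex perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
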