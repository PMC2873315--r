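Package: discrimODE
Title: Optimal Experiment Design for Discriminating Rival ODE Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs experiments that maximally discriminate between two
    rival ordinary-differential-equation models of the same biochemical
    network.  Three methods maximize the L2 norm of the difference between
    the models' outputs: choice of a common initial condition (via the
    observability gramian of the linearized difference system or a
    sum-of-squares storage-function certificate), choice of a unit-energy
    stimulus profile (via the frequency-response peak, with an SOS upper
    bound on the nonlinear L2-gain), and choice of settable parameter values
    within boxes (structural design, via a parametric storage certificate).
    Includes a first-order conic solver for the underlying semidefinite
    programmes, nonlinear simulation oracles, and the classic two-model
    Dictyostelium chemotaxis adaptation case study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    compiler,
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
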