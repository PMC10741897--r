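Package: fohnn
Title: Fractional-Order Memristive Hopfield Neural Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and dynamic analysis of a four-neuron Hopfield
    neural network under electromagnetic radiation, modelled by coupling a
    flux-controlled memristor to one neuron and formulating the circuit as
    a Caputo fractional-order system. Provides a generic
    Adomian-decomposition (generalized power-series) integrator for Caputo
    systems of order 0 < q <= 1, the memristive Hopfield model with its
    linear/nonlinear decomposition and Jacobian, equilibrium location with
    the fractional-order stability criterion, Lyapunov-exponent spectra
    and bifurcation scans with attractor classification, a flux-controlled
    memristor with pinched-hysteresis diagnostics, and a two-term
    reduced-step emulation of a fixed-point hardware datapath with
    truncation-error audits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
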