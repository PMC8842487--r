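Package: micellex
Title: Single-Chain Mean-Field Simulation and Eyring Kinetics of Micelle Chain Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained single-chain mean-field (SCMF) theory for triblock
    copolymer (poloxamer) micelles: equilibrium micellization scans (chemical
    potential curves, preferred aggregation number, critical micelle
    concentration), dynamic Monte Carlo exchange kinetics with tagged-chain
    correlation functions F(t), radial conformational diagnostics of the exit
    pathway, and a three-parameter modified Eyring kinetic model with
    closed-form solution, asymptotic regime analysis, nonlinear fitting and
    universal master-curve collapse of relaxation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    deSolve,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
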