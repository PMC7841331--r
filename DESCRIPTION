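Package: chemoctrl
Title: Cell-Cycle-Specific Chemotherapy PK/PD Dynamics, Controllability and
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and control-theoretic analysis of bilinear
    compartment models of tumor growth under cell-cycle-specific
    chemotherapy. Couples a first-order pharmacokinetic equation with
    dose-dependent clearance to Emax/sigmoid Hill pharmacodynamics,
    evaluates L1-type objective functionals over dosing schedules,
    performs the Kalman rank test for controllability of linear
    time-invariant systems (with a linearization bridge for the bilinear
    model), and runs Latin-hypercube global sensitivity studies of the
    concentration trajectory with per-time envelopes and per-parameter
    rankings. Includes a registry of reference simulation scenarios that
    reproduce the qualitative behaviors of the one-compartment study
    configuration from configuration alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
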