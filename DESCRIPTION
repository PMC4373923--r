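Package: tcellsim
Title: Twin Deterministic and Agent-Based Simulators of Naive T-Cell Ageing
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the age-related depletion of the naive T-cell
    repertoire under thymic involution with two paradigms built from the
    same compartmental model: a deterministic stock-and-flow (ODE)
    simulator integrated with fixed-step Runge-Kutta, and a stochastic
    agent-based simulator with rate-driven state transitions.  Ships five
    homeostasis scenarios (no peripheral proliferation, free thymic
    export, density-dependent naive death, density-dependent thymic
    export, and unrestricted), an activated-CD4+ lookup table generator,
    TREC (T-cell receptor excision circle) validation fixtures, Wilcoxon
    rank-sum comparison of the two simulators' trajectories, and an
    end-to-end study runner with CSV/JSON outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
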