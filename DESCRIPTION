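Package: agevuln
Title: Hybrid Agent-Based Simulation of Age-Dependent Neuronal Vulnerability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid agent-based/continuous simulator of age-dependent neuronal
    vulnerability in a C. elegans-parameterised stress-response network. Each cell
    agent carries a Hill-function molecular network (reactive oxygen species, tau
    load, and nine normalised stress-response activities spanning the mitochondrial
    and endoplasmic-reticulum unfolded protein responses, skn-1/Nrf2 and
    daf-16/FoxO signalling, and autophagy/mitophagy machinery) coupled to a
    stochastic pool of mitochondrion agents. A bifurcating phenotype state machine
    classifies cells from resilient through compromised states to an absorbing
    vulnerable state with rate-dependent death. The package provides steady-state
    dose-response and hysteresis analysis under clamped oxidative stress,
    population fold-change signatures, survival curves, human-age extrapolation,
    correlation against experimental fold-change tables, and a one-at-a-time
    normalised sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
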