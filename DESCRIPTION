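Package: p53combo
Title: Simulation and Optimization of Combined Radiotherapy and Mdm2-Inhibitor Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic (ODE) and stochastic (Gillespie) simulation of a
    p53-pathway reaction network with one-compartment Mdm2-inhibitor
    pharmacokinetics, for in-silico screening of fractionated radiotherapy
    protocols combined with Mdm2-inhibitor dosing. Provides critical
    irradiation dose search by bisection, apoptotic-fraction estimation from
    seeded stochastic ensembles with a species-scaling acceleration, and a
    two-step protocol optimizer that ranks schedules by the normal-to-cancer
    critical-dose ratio and verifies them stochastically against apoptotic
    fraction thresholds for cancer and normal cells.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
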