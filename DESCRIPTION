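Package: p53loop
Title: Deterministic and Stochastic Simulation of the p53-Mdm2 Negative
    Feedback Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the core negative feedback loop between the tumor
    suppressor p53 and its inhibitor Mdm2, modelled as four coupled ordinary
    differential equations (free p53, Mdm2 mRNA, free Mdm2 and the p53-Mdm2
    complex) without explicit transcriptional delay; oscillations arise from
    the nonlinearity of complex formation.  Provides equilibrium and linear
    stability analysis, stiff deterministic time courses with stress events,
    oscillation metrics (amplitude, period, spikyness), stress scenarios
    encoded as per-parameter fold changes including a DNA-damage scenario
    calibrated to published peak schedules, SNP309 promoter-variant modelling,
    two-dimensional phase diagrams with spikyness contours, local fold-change
    sensitivity curves, an exact Gillespie stochastic counterpart with
    concentration/molecule-count volume scaling, and SBML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
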