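Package: rtcafit
Title: Tumor and T-Cell Population Dynamics from Real-Time Impedance
    Cytotoxicity Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of impedance-based real-time cytotoxicity assays
    (cell-index traces) with a heterogeneous cancer/active-T/exhausted-T
    ordinary-differential-equation model. Provides a deterministic adaptive
    fourth-order Runge-Kutta integrator with nonnegativity enforcement, the
    standard impedance-assay statistics (normalized cell index, percent
    cytolysis, Killing Time with not-detected semantics), a
    macroevolutionary least-squares fitter implementing the two-stage
    growth-then-interaction calibration protocol, and a synthetic-data
    generator emulating the assay's timing, sampling and noise structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
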