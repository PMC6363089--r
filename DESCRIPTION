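Package: cbbkin
Title: Ensemble Kinetic Modeling and Metabolic Control Analysis of the
    Calvin-Benson-Bassham Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a 29-reaction kinetic model of the Calvin-Benson-Bassham
    (CBB) cycle embedded in the central carbon metabolism of the cyanobacterium
    Synechocystis sp. PCC 6803, samples thermodynamically feasible metabolite
    concentration sets (fMCSs) by log-space rejection sampling, parameterizes
    reversible Michaelis-Menten rate laws around each state by Monte-Carlo
    sampling of binding constants with exact Vmax calibration to an input
    steady-state flux, classifies local stability from the eigenvalues of the
    reduced Jacobian, computes scaled concentration and flux control
    coefficients, and aggregates and clusters the resulting control patterns
    across the ensemble. Includes synthetic generators for every external
    input (steady-state flux vectors, concentration-range tables, toy models
    with closed-form control coefficients) and a deterministic, checkpointed
    pipeline driver.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
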