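Package: duspkin
Title: Kinetic Modelling of DUSP-Regulated HER2/MAPK Signalling Under
    Herceptin
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mass-action kinetic model of HER2/MAPK signalling with
    dual-specificity phosphatase (DUSP) negative feedback and a survival
    readout, for studying how DUSP inhibition re-sensitises
    Herceptin-resistant HER2-positive breast cancer cells to the drug.
    Provides the model core (derivatives, closed-form steady states,
    three DUSP-induction topologies), stiff ODE simulation and inhibition
    scans over the DUSP inactivation rate, survival-trajectory regime
    classification, seeded synthetic cell-count and qPCR data generators,
    least-squares parameter recovery, delta-delta-Ct quantification, a
    two-sample Z-test, model-experiment concordance scoring, and a
    configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
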