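Package: rudose
Title: Traceable Absolute Dosimetry for Ru-106 Ophthalmic Plaque Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for traceable absorbed-dose-to-water dosimetry of Ru-106
    CCB ophthalmic brachytherapy plaques with direct-reading detectors.
    Processes raw electrometer reading sessions (background subtraction,
    bidirectional merging, decay referencing), converts net readings to dose
    via external-beam calibration coefficients with depth-dependent beam
    quality correction factors, forms alanine perturbation-factor chains from
    staged geometry doses, combines GUM-style type A/B uncertainty budgets in
    quadrature, extrapolates and normalizes depth-dose curves, and tests
    agreement against vendor certificates at expanded uncertainty. A seeded
    synthetic source model generates CCB-like sessions, certificates and
    geometry chains so the whole chain is testable without measurement data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
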