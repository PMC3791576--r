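Package: chromval
Title: Stability-Indicating HPLC Method Validation and Measurement
    Uncertainty Budgets
Version: 0.1.0
Authors@R:
    person("Analytical", "Methods Lab", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Tools for validating a stability-indicating reversed-phase
    HPLC assay and for assembling the ISO-GUM measurement uncertainty
    budget from the validation data.  Provides a seeded synthetic-data
    generator (linear detector response, first-order forced-degradation
    kinetics, Gaussian and exponentially-modified-Gaussian chromatogram
    synthesis), peak detection and integration with USP system-suitability
    metrics (theoretical plates, tailing factor, resolution), linear
    calibration with inverse prediction and its standard error, ICH-style
    validation statistics (precision, accuracy, recovery, limit of
    quantification, robustness), and the four-component expanded
    uncertainty budget with coverage factor k.  An end-to-end pipeline
    and command-line interface orchestrate generation, integration,
    calibration, validation and budgeting into a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
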