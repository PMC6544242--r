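Package: msval
Title: Total-Error Validation Statistics for Targeted LC-MS/MS Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for bioanalytical method validation of
    multiplex MRM (multiple reaction monitoring) LC-MS/MS assays: calibration
    with three candidate response models and inverse prediction, trueness and
    variance-component precision (repeatability, intermediate precision),
    beta-expectation tolerance intervals and accuracy (total-error) profiles
    with interpolated quantification limits, Matuszewski matrix-effect,
    extraction-recovery and process-efficiency statistics with internal-standard
    normalization, signal-to-noise detection limits and the replicate-precision
    instrument detection limit, and carryover, ion-ratio, stability and
    anticoagulant-comparison decision rules. Includes a synthetic multiplex-MRM
    data generator with known ground truth so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
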