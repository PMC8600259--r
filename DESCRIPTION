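Package: rtsprt
Title: Early Stopping for Real-Time Task fMRI with Sequential Probability
    Ratio Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistically driven early stopping for real-time block-design
    task fMRI. Voxelwise general linear model contrast estimates are updated
    incrementally as brain volumes arrive, with a heteroscedasticity- and
    autocorrelation-robust sandwich variance estimator. Each voxel runs a
    truncated, two-stage Wald sequential probability ratio test whose
    alternative hypothesis is calibrated from first-stage variance estimates,
    and a global percent-classified rule terminates stimulus conditions early.
    Includes a block-design BOLD simulator with known ground truth (double-gamma
    hemodynamic responses, low-frequency drift, AR(1) noise), a volume-streaming
    harness, NIfTI map output, and overlap metrics for comparing early-stop and
    full-duration activation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    sandwich,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
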