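Package: thermobreath
Title: Contactless Respiratory-Rate Estimation from Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating respiratory rate from low-resolution thermal
    video of the face. Implements decoding of dual-stream radiometric frames into
    calibrated temperature maps, a scheduled-detection workflow with
    constant-velocity Kalman tracking of the nostril bounding box, coldest-pixel
    breathing-signal extraction, zero-phase Butterworth band-pass filtering with
    an adaptive MAD-hysteresis breathing-phase state machine, and inter-breath
    interval validation with weighted and exponential smoothing of the reported
    rate. Includes a ground-truthed synthetic thermal-scene generator, peak and
    spectral baseline estimators, and evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
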