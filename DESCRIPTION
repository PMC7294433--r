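Package: pvmprv
Title: Remote Pulse Rate Variability from RGB Traces via Periodic Variance Maximization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for camera-based (remote photoplethysmography) pulse rate
    variability measurement. Extracts a blood volume pulse signal from
    three-channel color traces by Periodic Variance Maximization, a
    generalized eigenvalue decomposition of the lagged-covariance/covariance
    matrix pair scanned over the human heart-rate band. Provides three
    systolic peak detectors (adaptive two-window dual moving averages, slope
    sum function, and rule-based local maxima), inter-beat interval and
    200 Hz interpolated pulse-rate-variability series with time and
    frequency domain features (SDNN, RMSSD, LF and HF band powers), a full
    evaluation-metric suite against ground-truth peak annotations, and a
    seeded synthetic-signal generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
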