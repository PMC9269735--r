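Package: gaitsense
Title: Gait and Balance Feature Extraction and System Agreement for
    Wearable and Motion-Capture Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gait and postural-sway features from waist-worn
    smartphone accelerometer recordings and from pelvis/feet motion-capture
    position traces, and compares measurement systems statistically.
    Implements band-pass-filtered step detection on the acceleration norm
    with grid-search calibration of the detector against ground-truth mean
    stride intervals, step-wise double integration to velocity and
    displacement, lane-based mocap gait features with heading-drift
    correction, sway path length, ellipse area and PCA ellipsoid volume,
    and an agreement/pre-post statistical layer (Pearson strength classes,
    normality-gated paired tests, Bonferroni correction, extreme-outlier
    exclusion). Ships a synthetic-recording generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    rlang,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
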