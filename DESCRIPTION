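Package: fixem
Title: Analysis of Fixational Eye Movements from High-Resolution Gaze
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for analysing fixational eye movements in high-resolution
    gaze recordings: reading, zero-point calibration, segmentation and
    quality scoring of gaze time series; microsaccade detection with the
    Engbert-Kliegl velocity-threshold method, merging, displacement
    filtering and drift-episode coding; fixation-stability metrics
    (bivariate contour ellipse area, microsaccade rate, displacement and
    direction, drift path length and speed); two-dimensional kernel density
    maps of displacement vectors; and a seeded synthetic gaze generator
    with ground truth for end-to-end validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
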