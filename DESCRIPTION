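Package: avianradar
Title: Detection Performance Verification for Avian Radar Tracking Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to verify the detection performance of automated avian radar
    tracking systems using a radar-cross-section calibrated unmanned aerial
    vehicle (UAV) as a test target. Estimates the clock offset between GPS and
    radar data streams, pairs radar plots with GPS truth positions and derives
    nondetections at the radar scan cadence, maps ground clutter as terrain in
    line-of-sight of the radar, screens observations by altitude and flight
    tortuosity via segmented regression, fits binomial random-intercept models
    of detection probability over range and clutter, derives the calibrated
    detection range at a chosen detection probability, and extrapolates it to
    birds of arbitrary size through Swerling-1 detection theory and fourth-root
    radar-equation scaling of radar cross section. Includes a synthetic-data
    generator that emulates calibration test flights with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
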