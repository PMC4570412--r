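Package: fmassess
Title: Automated Upper-Limb Motor Function Assessment from Multi-Sensor
    Movement Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automating upper-limb motor-function assessment in
    the style of the Fugl-Meyer Assessment (FMA). Reads multi-sensor
    movement recordings (depth-camera skeleton streams, wrist-worn inertial
    measurement units, flexion-sensor gloves, and grip-pressure sensors),
    preprocesses them (movement-speed normalization, median filtering,
    automatic movement-end detection), extracts kinematic and inertial
    features per a declarative test registry, scores each test movement
    0/1/2 with per-test linear support-vector machines or a three-layer
    backpropagation network, and aggregates per-test scores into an
    FMA-style total with agreement reporting. A seeded multi-sensor
    movement simulator generates recordings at three impairment levels so
    the whole pipeline can be exercised without sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
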