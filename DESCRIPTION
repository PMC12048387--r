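Package: kneetorque
Title: Piezoelectric Wearable Knee-Torque Monitoring and Auxetic Patch Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for piezoelectric wearable knee-joint torque
    monitoring: a calibrated synthetic signal generator for labelled
    flexion datasets, short-time Fourier transform mean-spectrum feature
    extraction with physiological artefact suppression, a lightweight dense
    neural network for torque/angle/load classification and regression with
    probability-weighted continuous decoding and user fine-tuning, a
    streaming inference harness with circular buffering and threshold
    alerting, characterization formulas for tensile and electrical bench
    tests, and inverse design of the rotating-square auxetic sensor patch
    via a plane-stress finite element solver and Nelder-Mead optimization.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    signal,
    pracma,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    xml2
Config/testthat/edition: 3
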