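Package: qtcohort
Title: Inter-Manufacturer Comparison of Automated QT/QTc Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for comparing automated QT and RR interval
    measurements between ECG machine manufacturers: bivariate-normal
    ellipse outlier gating on (QT, RR) pairs, fitting and validation of
    heart-rate correction formulas (Bazett, Fridericia, Framingham,
    ECAPS12, and log/raw regression-derived corrections anchored at
    RR = 1 s), and estimation of the between-device QT offset by
    covariate-adjusted regression. Includes a calibrated synthetic cohort
    generator emulating the stratified structure of large resting-ECG
    datasets so every stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
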