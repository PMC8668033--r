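Package: biokin
Title: Biokinemetric-Triangle Analysis of Segmental Spine Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for landmark-based analysis of segmental spine
    kinematics with the biokinemetric triangle: calibration of sagittal
    radiographic landmark coordinates, per-segment range-of-motion curves
    (triangle area versus percentage of section movement), delta-S/S-max
    segment signatures and spine number series, reproducibility assessment
    via a Gaussian plug-in Bayes error rate, worst/best segment detection
    against a reference surrogate of healthy motion geometry, implant
    height recommendation by virtual best-into-worst segment substitution,
    prediction of adjacent-level motion redistribution after implantation,
    and correlation of adjacent-level range-of-motion change with
    patient-reported outcome change.  Includes a seeded synthetic-spine
    generator that emulates calibrated landmark trajectories of cervical
    and lumbar sections for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
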