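Package: iscee
Title: Energy Expenditure Estimation from Wearable Sensors in Ambulatory
    Incomplete Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating energy expenditure (EE) of ambulatory
    individuals with an incomplete spinal cord injury from multi-site
    wearable inertial and barometric sensor recordings. Covers signal
    preprocessing (Butterworth filtering, stream alignment, one-minute
    windowing), a named feature bank of statistical and high-level
    features (activity counts, gyroscope-based step detection, limb-use
    laterality, cross-correlation, altitude change), resting energy
    expenditure prediction equations, a distance-weighted k-nearest
    neighbour activity-class gate, class-conditional EE regression fitted
    by minimising summed squared relative errors, an ensemble of
    Levenberg-Marquardt-trained single-hidden-layer neural networks,
    agreement and equivalence statistics (Bland-Altman, paired TOST), and
    the translation of institutional physical-activity guidelines into
    daily step goals. A seeded synthetic-cohort generator makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
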