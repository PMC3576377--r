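Package: imugait
Title: Wearable Inertial-Sensor Gait Analysis, Feature Banks and
    Cross-Validated Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing recordings from shoe-mounted six-channel
    inertial sensors (3-axis accelerometer, 3-axis gyroscope) captured
    during standardized motor tasks: a 10-meter walk, heel-toe tapping and
    foot circling. The package segments individual steps from the
    gyroscope signal, instantiates a 694-dimensional bank of step,
    sequence and frequency features per subject, reduces it by
    information-gain ranking plus sequential forward selection, and
    evaluates linear discriminant, AdaBoost and support-vector classifiers
    under stratified 10-fold cross-validation with balanced classification
    rate, sensitivity, specificity and positive predictive value. A
    synthetic gait simulator generates two-group cohorts with controllable
    effect sizes so the complete pipeline can be exercised without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
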