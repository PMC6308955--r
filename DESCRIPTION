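Package: stridekit
Title: Stride Length and Velocity Estimation from Foot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-stride length and mean velocity during running from
    a shoe-embedded six-axis inertial measurement unit (triaxial accelerometer
    and gyroscope). Implements four estimators: a stride-time lookup using
    gender-specific step functions of relative stride length, an
    accelerometer-only quadratic regression on a multi-channel absolute
    integration value, a zero-velocity-update dedrifted strapdown trajectory
    reconstruction, and a convolutional network regressor on raw stride
    windows. Includes threshold-based stride segmentation from dorsoventral
    acceleration, a synthetic running-stride simulator that produces IMU
    signals with exact ground-truth kinematics, and agreement statistics
    (mean error, MAPE, MAE, Bland-Altman limits of agreement,
    leave-one-subject-out folds, cumulative distance error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
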