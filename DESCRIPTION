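Package: sedbout
Title: Sedentary-Behaviour Bout Detection from a Lower-Back Triaxial Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies sitting, lying and upright bouts from a single
    lower-back triaxial accelerometer (Axivity AX6 / OmGui CSV exports) using
    trunk tilt angles and movement-intensity thresholds with semi-adaptive
    sitting/lying labelling. Includes zero-phase Butterworth preprocessing,
    shape-preserving (pchip) resampling of drifting clocks, synchronisation-tap
    detection, a scripted-protocol signal simulator with ground-truth
    annotations, and a validation toolkit: frame-level confusion metrics,
    ICC(2,1), Bland-Altman limits of agreement, and absolute (percentage)
    duration errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    jsonlite,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
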