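Package: jtpeak
Title: Automated Measurement of the J-Tpeak and Tpeak-Tend ECG Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated delineation of the T-wave on the vector magnitude
    lead of the 12-lead electrocardiogram for cardiac safety assessment.
    Implements the full measurement chain: baseline wander removal by cubic
    spline interpolation, QRS trigger detection, median beat construction
    with upsampling to 1 kHz, derivation of orthogonal X/Y/Z leads and the
    vector magnitude lead, two-stage T-wave delineation (derivative-based
    peak/slur candidate detection, decision-tree slur relevance
    classification, cleanup rules, tangent-method T-wave offset with
    energy-cost refinement), interval measurement (QT, J-Tpeak, Tpeak-Tend)
    with heart-rate correction, a synthetic ECG generator with analytic
    ground-truth fiducials, and method-comparison statistics (Bland-Altman,
    intra-time-point variability, time-profile agreement).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
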