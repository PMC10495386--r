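Package: insoleval
Title: Validation and Reliability Analysis of Pressure-Insole Force and
    Centre-of-Pressure Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for validating wireless plantar-pressure insoles
    against laboratory force plates. Computes vertical ground-reaction
    force (vGRF), peak pressure and centre-of-pressure (COP) trajectories
    from raw sensel pressure frames, synchronizes and resamples
    multi-rate recordings, segments movement cycles (squat, jump,
    sit-to-stand, walking, stair ambulation) from the vGRF signal,
    time-normalizes cycles to 101 points and extracts per-cycle ranges,
    and evaluates between-system agreement (Bland-Altman limits of
    agreement with normality branching) and test-retest reliability
    (two-way random-effects consistency ICC, SEM, reliability-study
    sample size). Includes a synthetic-data generator that renders
    ground-truth activity waveforms as paired insole and force-plate
    recordings with configurable measurement bias, so every stage is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
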