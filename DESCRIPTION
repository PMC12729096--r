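Package: atcgaze
Title: Gaze-Based Mental Workload and Conflict-Resolution Analysis for
    Simulated En Route Air-Traffic Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 30 Hz remote eye-tracking recordings from
    simulated en route air-traffic control. Detects blinks (simultaneous
    both-eye data loss of 100-600 ms) and fixations (dispersion-threshold
    I-DT, 1 degree for at least 100 ms), accounts fixation time over static
    screen regions (active sector, out-of-sector airspace, flight-plan sheet)
    and over dynamic per-aircraft regions, derives session-level mental
    workload indices (pupil diameter, blink dynamics, ISA, NASA-TLX) with
    repeated-measures statistics, checks en route separation minima (1,000 ft
    / 5 NM) against scripted traffic scenarios, classifies conflict outcomes,
    and infers solver/non-solver differences with Mann-Whitney tests and
    forward-stepwise logistic regression. A seeded synthetic cohort generator
    (scenarios, gaze streams, intervention logs, subjective scores) makes the
    whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    car,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
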