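Package: skiemg
Title: On-Snow Electromyography and Turn-Cycle Analysis for Alpine Ski Training
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical analysis of multi-channel on-snow
    recordings from alpine ski training: surface EMG conditioning (Butterworth
    band-pass, artifact rejection, baseline removal, sliding RMS envelope,
    normalization to maximal voluntary contraction), turn-cycle segmentation
    from the trunk accelerometer resultant, per-turn EMG and kinematic scalar
    metrics (RMS amplitude in percent MVC, mean power frequency, burst
    duration, joint angle extrema and angular velocities, turn and run times),
    and random-intercept mixed-model inference with intraclass-correlation
    effect sizes, coefficient-of-variation repeatability decomposition and
    estimated marginal means. A seeded synthetic-session generator with known
    ground truth supports end-to-end verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    emmeans,
    glmmTMB,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
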