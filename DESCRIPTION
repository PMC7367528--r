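Package: liftlight
Title: Offline Engine for Sonification and Ambient-Light Resistance-Exercise Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable engine for closed-loop resistance-exercise
    feedback driven by a single vertical hand-position signal. Provides
    double-exponential (Holt) smoothing with jitter and deviation clamps,
    turning-point detection and repetition segmentation, per-set
    contraction-time and endpoint-variation metrics, a phase-aligned
    sinusoidal reference movement model, velocity-error pitch-transposition
    sonification with endpoint earcons, a paced-breathing light channel with
    breath-hold (Valsalva) detection from a respiration-audio envelope, and a
    seeded synthetic-data generator for motion traces and breath envelopes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
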