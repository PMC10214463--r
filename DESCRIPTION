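Package: sealtrip
Title: Dive Records, Morphometrics and Bioenergetics for Pinniped Biologging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for processing time-depth-recorder (TDR) records from
    free-ranging pinnipeds: zero-offset correction, dive detection and per-dive
    statistics (depth, duration, bottom time, wiggles, post-dive intervals),
    track interpolation and distance metrics, solar-elevation day/night
    classification, truncated-cones body composition and surface-area-to-volume
    estimation, prey-capture-attempt (jaw-motion) aggregation, trip-level
    behavioural summaries, and a bioenergetics layer for tissue-energy
    partitioning, field-metabolic-rate integration and fever-cost scenarios.
    Includes a seeded synthetic-trip generator with ground-truth dive tables,
    including an illness regime with extended surface intervals and suppressed
    foraging, for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, geosphere
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
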