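Package: motoprofile
Title: Motorcyclist Driving Behavior Profiling from GPS Speed Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for naturalistic motorcycle driving-behavior analysis from
    smartphone speedometer GPS logs. Parses and cleans app-exported speed
    traces, converts them to metric units, derives per-interval acceleration
    and braking, learns normal/aggressive/dangerous severity thresholds from
    the empirical distribution (mean + s.d. and mean + 2 s.d.), classifies
    every sample and speed reading, and aggregates per-driver and cohort risk
    profiles including over-speed event shares. A seeded synthetic trip
    generator with ground-truth label ledgers makes the whole pipeline
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
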