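Package: occlutrack
Title: Task-Anchored Tracking Quality for Occluded Visual Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how well gaze tracks a temporarily
    occluded moving target. Implements a psychometric task-accuracy model
    that links absolute gaze-target displacement and slippage at target
    reappearance to success in a four-alternative forced-choice
    discrimination probe, maximum-likelihood fitting of the model per
    participant with a reduced-model AIC comparison ladder, percentile
    bootstrap summaries, and a derived tracking-quality metric evaluated
    continuously over occlusion. Includes a synthetic-data generator that
    emulates a ramp-with-occlusion tracking experiment (smooth pursuit
    with decay, catch-up and jump-ahead saccades, confidence dropouts) so
    the full pipeline is testable without recorded eye-tracking data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
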