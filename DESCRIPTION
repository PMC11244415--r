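Package: tapmetrics
Title: Finger-Tapping Test Metrics from Wearable Accelerometer Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for instrumented finger-tapping tests recorded
    with wearable tri-axial accelerometers. Converts raw per-finger
    acceleration traces into tap events by prominence-based peak detection,
    derives single-finger metrics (tap counts, inter-tap intervals, linear
    fatigue slope, windowed amplitude excursion), dual-finger coordination
    metrics (simultaneity/alternation timing and classification), and
    cohort-level statistics (placement-repeatability coefficient of
    variation and the Sample Fatigue Percentage computed from a Gaussian
    model of fatigue slopes). Includes a ground-truthed synthetic trace
    generator so the full pipeline can be exercised and validated without
    sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
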