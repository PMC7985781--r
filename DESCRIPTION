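Package: uxpand
Title: Prediction from Unsynchronized Derivative Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the forward evolution of a smooth signal
    from its value and the values of its time derivatives observed at
    arbitrarily different (unsynchronized) times, as happens when different
    sensors report a physiological parameter and its rates of change with
    different latencies. Implements the unsynchronized power-series
    expansion (U-expansion) that generalizes the Taylor series to staggered
    detection schedules, its coefficient algebra in exact rational
    arithmetic for uniform-lag schedules, truncation-error analysis against
    the Taylor series, a backward finite-difference baseline, and a seeded
    generator of synthetic sensor-like derivative observation streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
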