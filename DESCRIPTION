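Package: gaitsync
Title: Closed-Loop Simulation of Gait-Music Phase Alignment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates an adaptive music player coupled to a stochastic walker
    and evaluates how well footfalls align with musical beats. Four alignment
    strategies are implemented as per-step controllers (period-adaptive,
    period-fixed, phase-aligned song starts, and continuous phase-adaptive
    tempo nudging), together with a synthetic walker whose entrainment follows
    a coupled-oscillator (HKB-style) phase-correction map, a 100 Hz sensor
    quantisation model, and a circular-statistics toolkit (mean resultant
    vector, circular variance, angular deviation, circular skewness and
    kurtosis, Rayleigh, Hodges-Ajne and two-sample Watson U2 tests).
    Experiments are reproducible, configuration-driven, and emit tidy event
    logs and summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
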