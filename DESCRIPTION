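Package: synbold
Title: Incremental Syntactic Complexity Metrics and fMRI Encoding Models
    for Spontaneous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes word-by-word incremental syntactic complexity metrics
    (top-down, bottom-up, left-corner, open-nodes, and two production-specific
    strategies: early top-down and head-driven chunked counting) from
    constituent and dependency parses of spontaneous speech, converts them into
    scan-resolution regressors by convolution with the canonical double-gamma
    hemodynamic response function, and relates them to region-of-interest BOLD
    timeseries and to speech timing (pauses, word durations) with
    mixed-effects encoding models compared by AIC and likelihood-ratio tests.
    Includes a synthetic-data generator (PCFG corpora, word timings, BOLD
    forward model) with known ground truth so the full pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    car,
    emmeans,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
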