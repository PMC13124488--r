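Package: isletca
Title: Islet Calcium Imaging Analysis and Functional Beta-Cell Subpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pancreatic-islet calcium imaging recordings
    at single-cell resolution. Reads per-ROI fluorescence time series as
    exported by ImageJ Multi Measure, conditions the signals (moving-average
    smoothing, general-baseline fold change, piecewise-linear adaptive
    baseline detrending), quantifies global islet dynamics (apparent and
    trapezoid area under the curve, first-phase amplitude and activation
    time, second-phase wave frequency, amplitude and width), and classifies
    functional beta-cell subpopulations: first-responders, highly connected
    "hub" cells from a binarized coactivity network with a circular-shift
    permutation null, and leader cells from per-wave activation latencies.
    Includes a seeded synthetic islet-recording generator with planted ground
    truth so every stage can be validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
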