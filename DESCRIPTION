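Package: titrace
Title: Time-Intensity Analysis of Continuous Perceptual Rating Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-intensity (TI) analysis of continuously sampled
    visual-analogue-scale (VAS) intensity traces from sensory and haptic
    perception studies. Extracts the standard TI curve parameters (maximal
    intensity, onset, extinction, plateau, slopes, areas under the curve),
    fits penalized-spline smooths of perceived intensity over time with
    pointwise confidence bands and Wald tests, compares TI parameters across
    between-subject conditions with Kruskal-Wallis and Dunn post-hoc tests
    plus common-language effect sizes, and compares sensation-descriptor word
    distributions with one-sample chi-square tests. Includes a synthetic
    study generator with analytically known ground truth so the full pipeline
    is testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
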