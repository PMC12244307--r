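Package: trigrowth
Title: Fish Growth Estimation from Age-at-Length, Mark-Recapture and
    Length-Frequency Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates von Bertalanffy growth parameters for river fish from
    three independent data sources: age-at-length records read from scales
    (frequentist nonlinear least squares and Bayesian fits with literature
    priors), mark-recapture length increments via the Fabens
    reparameterization, and length-frequency time series via electronic
    length-frequency analysis (ELEFAN) with a genetic-algorithm search and
    bootstrap confidence intervals. Includes a synthetic-data generator that
    emulates a seasonal riverine monitoring programme, scale-ageing helpers,
    and an end-to-end comparison pipeline that fits all five model variants
    and overlays their growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    coda,
    jsonlite,
    yaml,
    stats,
    withr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
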