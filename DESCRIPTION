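Package: tpodr
Title: Transcriptomic Points of Departure from Dose-Series RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives transcriptomic points of departure (tPODs) from
    dose-series gene-expression count data. Implements the full chain from
    negative-binomial differential expression and Williams trend
    prefiltering through per-gene benchmark-dose (BMD) modeling with a
    continuous model suite (linear, polynomial, power, Hill, exponential),
    profile-likelihood BMD confidence bounds, BMDExpress-style
    postfiltering, and percentile- and density-mode-based tPOD summaries.
    Ships a negative-binomial dose-series simulator with per-gene ground
    truth for method validation, GMT-based over-representation analysis,
    and larval locomotion metrics (thigmotaxis, startle) with
    Dunnett-style many-to-one comparisons.
License: MIT
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
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    multcomp,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
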