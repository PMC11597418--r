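Package: paddynr
Title: Paddy Field Water Balance and Nitrogen Runoff Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the daily ponding-water balance and surface-water
    nitrogen dynamics of flooded rice fields to quantify nitrogen runoff
    losses under alternative fertilization strategies, including green-manure
    (Chinese milk vetch) substitution with reduced mineral nitrogen and straw
    return. Provides a monthly two-state first-order Markov chain plus
    two-parameter Gamma stochastic weather generator, drought-index year
    classification, RMSE / index-of-agreement / Nash-Sutcliffe model
    evaluation, grid-refinement trial-and-error calibration, multi-decade
    scenario analysis stratified by rainfall year type, and a synthetic-data
    generator emulating field observation campaigns.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
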