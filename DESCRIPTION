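Package: seatrace
Title: Propagating Fisheries Management Scores Through the Global Seafood
    Trade Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the sustainability of each country's seafood
    consumption from the sustainability of its production and bilateral
    trade flows.  Country-level Fisheries Management Index (FMI) scores
    are propagated through a trade network built from food-balance-sheet
    and bilateral trade-record tables, with a global production-weighted
    score regularizing untraceable re-exports.  Includes three
    sensitivity derivations for the domestic share of consumption, a
    gap-filling regression for countries without surveyed FMI, disparity
    and regression summaries of production versus consumption
    sustainability, and a provenance-tracked synthetic trade-world
    generator that supplies ground truth for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
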