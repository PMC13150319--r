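Package: conduitr
Title: Conduit Number and Diameter Allometry Along Woody Stems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether xylem conduits furcate (multiply
    distally) along woody stems. Provides standardized major axis (SMA)
    regression with slope tests, multiple regression for segment-length
    effects, tip-to-base conduit widening regression, phylogenetic reduced
    major axis regression under Brownian motion with maximum-likelihood
    estimation of Pagel's lambda, and baseline furcation predictors (fixed
    internode spacing, geometric internode contraction, da Vinci area
    conservation, Murray's law) compared against observed tip conduit
    counts. Includes a synthetic-data generator emulating branch-level
    measurement designs so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
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
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
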