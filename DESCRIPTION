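Package: deforbase
Title: Sensitivity Analysis of Jurisdictional Deforestation Emission Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how sensitive jurisdictional avoided-deforestation
    emission baselines are to defensible methodological choices. The package
    enumerates a grid of permitted method combinations (projection approach,
    forest dataset, historical reference period, carbon sources), computes a
    baseline in tCO2e/yr for every valid combination as the product of a
    projected deforestation rate and an average forest carbon density, and
    summarises the spread with coefficients of variation, hindcast forecast
    errors, quadrature-propagated uncertainties, ANOVA/Tukey level comparisons,
    and bootstrapped random-forest variable importance. A seeded synthetic
    jurisdiction generator with known ground truth stands in for global
    geospatial inputs so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    MASS,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
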