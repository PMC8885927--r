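Package: pahcast
Title: Characteristic Congener Selection and Emission-Based Prediction of
    Total PAH Concentrations in Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for chemometric analysis of the sixteen priority polycyclic
    aromatic hydrocarbons (PAHs) in freshwater sediments and emission
    inventories. Identifies characteristic congeners by hierarchical
    clustering of congener profiles with maximum-R2 representative selection,
    fits simple and multilinear surrogate models for the total PAH burden
    with the percent-sample-deviation (SDEV) error statistic, builds
    technology-split emission inventories from emission factors and activity
    data, and predicts total sediment PAH concentrations from congener
    emissions and octanol-water partition coefficients (logKow) via a linear
    transfer model. Includes a reproducible synthetic-data generator that
    emulates the subgroup structure of real emission-factor and sediment
    tables, so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
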