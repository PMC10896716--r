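Package: easidemand
Title: Censored EASI Food Demand Systems, Nutrient Elasticities and Policy
    Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates censored Exact Affine Stone Index (EASI) incomplete food
    demand systems from household consumption panels, with homogeneity, symmetry
    and adding-up restrictions, a two-step probit censoring correction,
    instrumental variables for Stone-index and unit-value price endogeneity, and
    community-level correlated random effects.  Derives household-level
    expenditure and Marshallian/Hicksian price elasticities with simulated
    standard errors, maps them into nutrient-intake elasticities through food
    composition tables, scores household diet quality (nutrient adequacy against
    household requirements, WHO macronutrient balance, and a nutrient-rich food
    index), and microsimulates cash transfers and food price discounts with
    programme cost accounting.  A synthetic-data generator produces LSMS-style
    household panels from a known demand-system data-generating process so that
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
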