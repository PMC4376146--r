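Package: fairlink
Title: Deterministic Mother-Child Record Linkage for Clinical Data Warehouses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies mother-child dyads inside a clinical data warehouse
    extract by deterministic matching on normalized insurance, phone and
    address identifiers, followed by an oldest-eligible-female classification
    rule with a tie-break cascade. Includes identifier canonicalization
    (insurance account/member splitting, phone and address cleaning),
    configurable match strategies over identifier combinations, evaluation of
    linkage test characteristics (sensitivity, specificity, PPV, NPV, ROC
    operating points) against a reference standard, and a seeded synthetic
    EHR population generator that reproduces the documented failure modes of
    family linkage: individually numbered safety-net insurance plans, phone
    churn, and multi-unit addresses lacking unit numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
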