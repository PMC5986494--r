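Package: foplcea
Title: Cost-Effectiveness Modelling of Front-of-Pack Label-Driven Food Reformulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the population health and economic consequences of
    front-of-pack nutrition labelling through its effect on product
    reformulation. Estimates label-attributable energy-density changes with a
    difference-in-difference design, converts them to cohort-level energy
    intake, body-weight and BMI shifts, propagates the shifted BMI
    distribution through a proportional multi-state life table of
    obesity-related diseases to health-adjusted life years, and combines
    intervention costs with averted treatment costs into incremental
    cost-effectiveness ratios with Monte Carlo probabilistic sensitivity
    analysis and cost-effectiveness planes. Includes a synthetic-data
    generator emulating the product, consumption, population, disease and
    cost tables the analysis consumes.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
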