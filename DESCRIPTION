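Package: canasta
Title: Nutritional Adequacy of Emergency Food Baskets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for municipal emergency food-basket registries:
    food-composition accounting with Atwater energy factors, caloric-distribution
    percentages, deficit/adequate/excess classification against Acceptable
    Macronutrient Distribution Range (AMDR) standards (INCAP and INDECI),
    stratified sampling-design utilities with finite-population correction,
    and nonparametric group comparisons (Kruskal-Wallis with Dunn post-hoc
    tests and compact letter displays). Includes a synthetic registry
    generator emulating the structure of the Peruvian COVID-19 basic
    family basket reports, so the full pipeline is testable end to end
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
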