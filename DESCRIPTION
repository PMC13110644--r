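Package: osteocea
Title: Cost-Effectiveness Modelling of Osteoporotic Fracture Risk Assessment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of osteoporotic fracture risk assessment
    for adults with intellectual disabilities from a UK NHS perspective. Implements
    a screening-cascade decision tree feeding a nine-state annual-cycle Markov
    cohort model, incremental cost-effectiveness analysis (ICER, net monetary
    benefit, dominance classification), deterministic scenario analysis,
    probabilistic sensitivity analysis with moment-matched beta/gamma sampling,
    cost-effectiveness acceptability curves, and age/sex subgroup analyses.
    Includes a synthetic parameter-bundle generator, an individual-level
    microsimulation oracle for validating the cohort engine, and CSV/JSON
    reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
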