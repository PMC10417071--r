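Package: nutricea
Title: Cost-Effectiveness Analysis of Enteral Nutrition Support During
    Chemoradiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for three-arm enteral
    nutrition-support studies in esophageal cancer treated with concurrent
    chemoradiotherapy. Generates seeded synthetic patient-level cohorts
    calibrated to published group summaries, computes trial statistics
    (one-sample noncentral-t sample size, Kaplan-Meier survival, ANOVA and
    chi-square group comparisons), performs three-group propensity-score
    caliper matching on the logit scale, and evaluates strategies with a
    three-state Markov cohort model: discounted costs and QALYs, ICER
    efficiency frontier with dominance handling, net monetary benefit,
    one-way (tornado) sensitivity analysis, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    nnet,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
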