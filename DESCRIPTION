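Package: floraltherm
Title: Floral Temperature Patterns and Bumblebee Conditioning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for differential-conditioning
    experiments in which bumblebees learn to discriminate artificial flowers
    by their floral temperature patterns. Provides a visit-level foraging
    simulator with bout structure, feeder depletion and revisit-exclusion
    rules; scoring of landings into correct/incorrect actions and 10-visit
    windowed success rates on the arcsine square-root scale; maximum
    likelihood fitting of hierarchical learning-curve models with per-bee
    random intercepts and slopes; a stepwise AIC/deviance model
    simplification ladder with per-group learning tests; one-way ANOVA with
    Tukey post hoc letter groupings for the nonrewarding test phase; and
    generation of synthetic floral thermographs with within-flower
    temperature-pattern statistics and species-survey summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
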