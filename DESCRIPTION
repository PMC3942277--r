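Package: afcea
Title: Markov Cohort Cost-Utility Model for Stroke-Prevention
    Anticoagulation in Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Lifetime Markov cohort state-transition model comparing a direct
    oral anticoagulant (rivaroxaban) with vitamin-K antagonists for stroke
    prevention in non-valvular atrial fibrillation, from a third-party payer
    perspective. Implements the cohort engine over tunnel and chronic health
    states, quality-adjusted life-year and cost accumulation with discounting,
    incremental cost-effectiveness analysis with dominance classification,
    deterministic scenario and one-way sensitivity analyses, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves. Ships a
    fully specified base-case configuration, degenerate and randomised fixture
    generators, and an independent individual-level microsimulation used to
    validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
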