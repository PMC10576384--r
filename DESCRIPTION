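Package: crswnpCEA
Title: Cost-Effectiveness Modelling of Biologic Therapy in Chronic
    Rhinosinusitis with Nasal Polyps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model comparing biologic
    therapies (dupilumab, omalizumab, mepolizumab) against revision
    endoscopic sinus surgery for recalcitrant chronic rhinosinusitis with
    nasal polyps, from a third-party payer perspective in 2021 Canadian
    dollars.  Provides the deterministic base case with dominance and
    ICER ranking, probabilistic sensitivity analysis with beta-distributed
    inputs, cost-effectiveness acceptability curves and confidence
    ellipses, deterministic threshold-price search by bisection, and
    alternative dosing-frequency scenarios.  A synthetic model generator
    and an independent individual-level microsimulation oracle validate
    the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
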