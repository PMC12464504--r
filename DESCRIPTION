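Package: strokecea
Title: Trial-Based Cost-Effectiveness and Budget-Impact Analysis for
    Community Stroke Care Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-trial and post-trial economic evaluation of
    cluster-randomized chronic-disease management programs, built around a
    primary-care mHealth stroke secondary-prevention intervention in rural
    China. Computes per-participant costs in reference-year US dollars
    (consumer-price-index adjustment, adherence-discounted medication
    valuation, program-cost amortization), quality-adjusted life years by
    the area-under-the-curve method from EQ-5D-5L utilities with death and
    linear imputation handling, covariate-adjusted arm differences from
    mixed multilevel models with village random intercepts, incremental
    cost-effectiveness ratios with stratified cluster-bootstrap
    uncertainty, cost-effectiveness acceptability curves, one-way
    deterministic sensitivity (tornado) tables, and a national
    budget-impact model with standalone and public-health-integrated
    scale-up scenarios. Includes a synthetic cluster-randomized trial
    generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
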