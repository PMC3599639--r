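Package: adhereCEA
Title: Cost-Effectiveness and Cost-Utility Modelling for a
    Computer-Delivered HIV Adherence Intervention
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic model for the cost-effectiveness and
    cost-utility of a computer-delivered intervention that improves
    antiretroviral medication adherence. Implements a five-state,
    CD4-stratified health-state model with upward transition scenarios,
    itemized development and deployment cost ledgers (clinic kiosk and
    web delivery), medication-consumption and return-to-work adjustments,
    QALY computation against a willingness-to-pay benchmark,
    development-cost threshold solving, and multi-way sensitivity sweeps
    over effectiveness scenarios, effect durations, utilization levels
    and cost multipliers. A seeded synthetic-cohort generator provides
    patient-level inputs with the statistical structure the analysis
    assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
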