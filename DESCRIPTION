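Package: hgbiomonitor
Title: Mercury Biomonitoring Exceedance Classification and Probabilistic
    Health Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing mercury biomonitoring campaigns in
    mother-infant cohorts: validated cohort data handling (breastmilk,
    blood, urine and household food concentrations), classification
    against matrix-specific permissible limits, deterministic USEPA-style
    Average Daily Dose and Hazard Quotient computation for lactating
    mothers (dietary wheat route) and breastfed infants (breastmilk
    route), seeded Monte Carlo uncertainty propagation of the hazard
    quotient with lognormal concentration models, mother-infant transfer
    association statistics, GeoJSON point-layer export, and a calibrated
    synthetic-cohort generator so that the full pipeline runs without
    access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
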