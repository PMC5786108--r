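Package: cpinet
Title: Contact Networks from Close-Proximity Interaction Sensors in Hospitals
Version: 0.1.0
Authors@R:
    person("I-Bird", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse close-proximity interaction (CPI) records
    collected by wearable proximity sensors in hospital settings,
    with an emphasis on long-term care facilities. Provides readers and
    validators for 30-second CPI packet streams, rosters and
    recording-gap schedules; daily contact statistics (distinct daily
    contacts per person, cumulative daily contact duration per pair);
    ward-conditioned category mixing matrices; hourly temporal profiles
    split by day type and pair type; and a risk-factor analysis of
    dichotomized contact outcomes using logistic mixed models with
    ward-level random intercepts. A calibrated synthetic generator
    emulates a five-ward facility so every stage of the pipeline can be
    exercised and tested without access to restricted sensor data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
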