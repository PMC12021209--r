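Package: retinasim
Title: Discrete-Event Simulation of a Hospital Retinal Service in an
    Integrated Care System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-support simulator for NHS hospital retinal services
    (age-related macular degeneration, diabetic retinopathy and retinal vein
    occlusion pathways) embedded in an integrated care system. Provides a
    discrete-event kernel with capacitated resource pools and reproducible
    random streams, a monthly booking model of referral, diagnostics,
    consultation, treatment, follow-up and did-not-attend dynamics, demand
    forecasting with automatic model selection, staff-cost and national-tariff
    revenue ledgers, and scenario analysis (nurse injectors, diabetic
    retinopathy demand uplift, community virtual clinics) under common random
    numbers, with warm-up and replication-sizing diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
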