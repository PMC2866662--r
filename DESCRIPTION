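Package: hydroscreen
Title: Statistical Pipeline for Cell-Free Hydrogenase Screening Campaigns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative core of a microtiter-plate screen for [FeFe]
    hydrogenase mutants expressed by cell-free protein synthesis from
    single-molecule PCR products. Provides Poisson occupancy statistics
    for limiting-dilution design and most-probable-number estimation of
    template concentration, exponential oxygen-deactivation modelling
    with exposure-volume tuning, conversion of methyl viologen A578
    kinetic traces into hydrogenase activities and specific activities,
    residual-activity hit calling with per-plate wild-type normalization
    and 2-SD thresholds, CV-based detectability and Monte-Carlo power
    analysis, and a fully seeded synthetic-campaign generator so the
    whole pipeline is testable without wet-lab data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
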