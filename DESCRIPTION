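Package: retinasim
Title: Discrete Event Simulation of Hospital Retinal Injection Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for capacity and cost modelling of hospital medical-retina
    services delivering intravitreal anti-VEGF therapy. Generates synthetic
    patient-level visit records with a prescribed activity composition,
    calibrates pathway parameters (per-year injection and follow-up count
    distributions, discharge hazards, case mix, virtual-clinic eligibility)
    from such records, forecasts monthly arrivals with population-growth
    adjustment, and runs a discrete event simulation of the care pathway --
    appointment booking with did-not-attend rebooking, finite clinic
    resources, discharge, and optional diversion of monitoring visits to
    nurse-led virtual clinics -- under pro re nata or treat-and-extend
    regimens. Reports monthly activity, resource utilisation, costing,
    revenue and surplus, and baseline-versus-redesign percentage-change
    comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
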