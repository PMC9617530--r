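Package: clinicflow
Title: Discrete-Event Simulation of a Two-Week-Wait Breast Cancer Clinic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event simulation of patient flow through a UK
    two-week-wait (TWW) symptomatic breast clinic, with an optional
    primary-care risk-test triage stage that rules low-risk patients out of
    immediate referral. The model generates a synthetic stream of symptomatic
    patients, routes them through GP referral (immediate, delayed six-week
    return, or none), a queue-responsive clinic booking rule, and
    resource-constrained clinic sessions (initial assessment, mammogram,
    ultrasound, biopsy; rooms and role-specific staff), and summarises TWW
    target attainment, time to first clinic attendance, and overspill
    appointments across replicated trials. Includes scenario presets for
    standard care and two test-adoption scenarios, service-reconfiguration
    options, sensitivity sweeps, and a roster calibration routine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    yaml,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
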