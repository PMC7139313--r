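Package: tolbreak
Title: Detecting Tolerance Breakage from Serum Biomarker Time Courses Under
    Checkpoint Inhibitor Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal monitoring of immune checkpoint inhibitor
    (CPI) therapy from routine serum laboratory values. Normalizes marker
    series to percent of the upper limit of normal (ULN), detects rise
    episodes on irregularly sampled time courses, quantifies them by
    baseline-subtracted area under the curve, and classifies temporal
    coincidences of immune-activation markers (IL-6, CRP) with tumor markers
    (S100B, LDH) or organ-damage markers (CK, ALT, myoglobin) into
    tolerance-breakage, immune-related adverse event, and paradox calls.
    Includes a synthetic-cohort simulator built on a one-compartment marker
    clearance model with phasic post-dose immune pulses, immune-mediated
    tumor kill, corticosteroid suppression, and configurable patient
    archetypes, plus a packaged 17-patient melanoma cohort summary table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
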