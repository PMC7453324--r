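Package: edcflow
Title: Schema-Driven Electronic Data Capture Engine for Longitudinal Field Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-first electronic data capture (EDC) engine for
    epidemiological studies and randomized controlled trials. Study protocols
    are declared as data (data dictionary, forms schedule, eligibility
    formulas, trigger rules, consent routing, identifier scheme, randomization
    table) and compiled into an immutable study definition that the engine
    enforces at data-entry time: longitudinal visit and case-report-form
    scheduling, real-time eligibility evaluation with three-valued logic,
    age-routed consent with progression gating, randomization-table allocation
    with midline serial sampling, plausibility and replicate validation,
    multi-device capture with asynchronous change-log synchronization,
    role-based access control, electronic signing, a full audit trail, and
    deidentified flat-file export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
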