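Package: alphachain
Title: Decay-Chain Biodistribution and Efficacy Analysis for Actinium-225 Radioimmunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for preclinical targeted alpha-therapy studies with
    actinium-225 labelled antibodies. Provides a closed-form Bateman solver for the
    Ac-225 / Fr-221 / At-217 / Bi-213 serial decay chain, reduction of gamma-counter
    records to percent injected activity per gram (delayed francium-window parent
    quantification with 1 percent standards), one-phase decay fitting of continuous
    Bi-213 counting traces with decomposition of activity at dissection into free and
    parent-supported components, ellipsoid tumor-volume and doubling-time analysis with
    humane-endpoint event construction, Kaplan-Meier / log-rank survival comparisons,
    the group statistics used in such studies, and a seeded synthetic-data generator
    emulating counting traces, biodistribution cohorts and therapy cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    survival,
    Matrix,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
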