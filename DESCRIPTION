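Package: planrad
Title: Dose-Volume Histogram Metrics and Radiobiological Evaluation of
    Arc-Therapy Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating and comparing external-beam radiotherapy
    plans from their dose-volume histograms (DVHs). Reads and writes
    per-structure DVHs in a plain-text CSV dialect, converts between
    cumulative and differential form, extracts clinical dose-volume
    criteria (Dx%, VxGy, mean and maximum dose) with defined interpolation
    semantics, computes logistic tumour control probability (TCP) by the
    volume-weighted tumorlet product and Lyman-Kutcher-Burman normal-tissue
    complication probability (NTCP) with Kutcher-Burman effective-volume
    DVH reduction, and aggregates per-patient metrics into cohort
    comparison reports between delivery techniques. A seeded synthetic-DVH
    generator emulates prostate VMAT cohorts so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
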