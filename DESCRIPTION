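Package: actisym
Title: Longitudinal Wrist Actigraphy and Symptom Diary Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for longitudinal wrist-worn actigraphy
    coupled with daily symptom diaries in chronic pain cohorts. Reads and
    calibrates raw tri-axial acceleration, temperature and light streams;
    detects non-wear with a two-pass temperature plus movement algorithm;
    estimates nightly sleep-period windows, wake after sleep onset and the
    day-pair sleep regularity index; derives daily physical-activity and
    rest-activity-rhythm features (M10, L5, relative amplitude, intensity
    minutes, temperature cosinor); scores daily pain and Brief Fatigue
    Inventory diaries and end-of-cycle EHP-30 questionnaires; summarizes
    daily series per smartwatch cycle (quartile means, Teager-Kaiser energy,
    root mean squared successive differences); and estimates associations
    with repeated-measures correlations, partial correlations, AR(1) linear
    mixed models and pre/post-surgery change summaries. Includes a synthetic
    cohort generator with ground-truth wear, sleep and latent symptom labels
    so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tibble,
    zoo,
    nlme,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow
Config/testthat/edition: 3
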