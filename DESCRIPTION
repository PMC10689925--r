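Package: epicourse
Title: Longitudinal Natural-History Analysis of Seizure-Frequency Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative natural-history analysis of genetic
    epilepsy cohorts recorded as ordinal monthly seizure-frequency (SF)
    scores. Provides SF-score encoding and cohort-median imputation,
    Kaplan-Meier onset and remission analysis, k-nearest-neighbour
    longitudinal seizure forecasting with a permutation-based test of
    better-than-chance prediction and high/low-fidelity partitioning,
    patient-month comparative effectiveness of anti-seizure medications,
    a virtual clinical-trial simulator producing Observed Frequency of
    Trial Success (OFTS) curves, developmental milestone and standardized
    assessment summaries, and a seeded synthetic-cohort generator that
    emulates the statistical structure of such cohorts for testing and
    power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
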