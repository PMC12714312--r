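Package: prostoxcea
Title: Cost-Effectiveness Modelling of MicroRNA-Guided Radiation Therapy
    Selection in Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid decision-tree and Markov cohort model evaluating a
    germline microRNA assay (PROSTOX ultra) that stratifies prostate cancer
    patients by risk of late genitourinary toxicity before radiation therapy.
    Implements the nine-track treatment decision tree, a three-state
    (no-toxicity, toxicity, death) annual-cycle Markov engine with a
    toxicity-development taper and background mortality from a life table,
    per-arm cost and QALY aggregation, five-year cost-impact and lifetime
    cost-effectiveness (ICER/dominance) analysis, one-way deterministic
    sensitivity analysis with tornado ordering, probabilistic sensitivity
    analysis with gamma/beta moment matching, and cost-effectiveness
    acceptability curves. Includes a synthetic Gompertz-Makeham life-table
    generator calibrated to a target life expectancy, a patient-level
    microsimulation oracle for the cohort recursion, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
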