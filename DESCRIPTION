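Package: brainctrl
Title: Average Controllability Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-region average controllability of resting-state
    functional brain networks under a discrete-time linear network-control
    model, compares two cohorts region by region (pooled t-test,
    Mann-Whitney U, Benjamini-Hochberg FDR), and evaluates the significant
    regions as diagnostic biomarkers with a multilayer-perceptron
    classifier under stratified ten-fold cross-validation. Includes a
    seeded synthetic-cohort generator that emulates a two-group
    resting-state fMRI study (AAL-90 parcellation) with region-localized
    connectivity alterations, plus an end-to-end pipeline driver with
    plain-text artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
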