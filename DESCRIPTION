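Package: sprintkan
Title: Intermuscular Coherence and Kolmogorov-Arnold Network Modelling of
    Sprint Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sprint-cohort surface
    electromyography studies. Generates synthetic multi-channel sEMG with
    controllable band-limited common neural drive and phase velocities,
    extracts time- and frequency-domain EMG features (iEMG, RMS, median
    frequency), estimates intermuscular coherence in alpha/beta/gamma bands
    with significance thresholds, fits an interpretable Kolmogorov-Arnold
    Network with cubic B-spline edge functions (sparsity and entropy
    regularized L-BFGS training, pruning, symbolic compression into a
    closed-form equation), and runs the repeated-measures ANOVA stage with
    Greenhouse-Geisser correction, Bonferroni post hocs and partial
    eta-squared effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
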