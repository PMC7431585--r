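Package: alphalat
Title: Alpha-Band Lateralization Analysis for Retro-Cue Working-Memory EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of posterior alpha-band (8-13 Hz)
    lateralization in an auditory retro-cue working-memory task: a synthetic
    generator for the trial design, epoched EEG with injected lateralized
    alpha modulations, and behavioral responses; artifact rejection
    (kurtosis-based channel screening, iterative SD trial rejection, average
    re-reference, downsampling); complex Morlet wavelet time-frequency
    decomposition on a log-spaced frequency grid; the Alpha Lateralization
    Index contrasting hemispheres ipsilateral and contralateral to a
    lateralized memory item; a paired time-by-frequency cluster-based
    permutation test; and a statistical toolbox with repeated-measures ANOVA
    (Mauchly/Greenhouse-Geisser), Friedman and Wilcoxon tests, Hedges g
    effect sizes, uncapped FDR correction, JZS Bayes factors, and a
    Lilliefors normality gate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
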