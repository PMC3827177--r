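Package: erdvoice
Title: Sensorimotor Mu/Beta Desynchronization Analysis for Vocal Imitation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for studying voice-specific
    sensorimotor activity in EEG during a melody imitation task. Generates
    five-note melodic stimuli and synthesizes triangle-wave and vocal-like
    renditions; simulates a full synthetic cohort (64-channel EEG with
    condition-dependent mu and beta event-related desynchronization, EMG,
    blink and spike artifacts, sung-response pitch tracks); preprocesses
    recordings (high-pass filtering, mastoid re-referencing, regression-based
    blink removal, epoching, threshold/improbability/kurtosis artifact
    rejection); computes Welch-periodogram band power with pre-stimulus
    baseline subtraction per region of interest and time window; scores vocal
    imitation accuracy in cents; and runs the within-subject statistics
    (repeated-measures ANOVA with Greenhouse-Geisser correction, Tukey HSD and
    Fisher LSD post-hocs, paired Wilcoxon, permutation Spearman correlation,
    stimulus-feature multiple regression).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
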