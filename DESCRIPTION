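Package: opto2p
Title: Analysis Pipeline for Simultaneous Optogenetic Stimulation and
    Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for all-optical interrogation experiments in which
    neurons are optogenetically stimulated while their activity is read
    out by two-photon calcium imaging and, behaviorally, by saccadic eye
    movements. Models frame-locked gating of widefield stimulation
    against the resonant imaging scan (duty cycle, repetition frequency),
    schedules interleaved trial conditions, motion-corrects movies by
    template matching with normalized cross-correlation, extracts ROI
    fluorescence traces and delta-F-over-F responses, fits orientation
    tuning (ANOVA selection, circular-Gaussian curves, pixelwise
    orientation maps) and laser-intensity dose-response curves, generates
    spiral photostimulation trajectories and quantifies single-cell
    targeting specificity, and scores GO/NO-GO eye-movement behavior
    (saccade detection, latency, success rates, latency decomposition
    across pulse trains). Includes a synthetic-data generator producing
    ground-truth-labeled movies, trial schedules and eye traces so every
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
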