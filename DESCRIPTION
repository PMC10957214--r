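Package: thermofc
Title: Static and Dynamic Functional Connectivity of Brain ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional connectivity of
    cerebral-blood-volume (Doppler) ROI time series recorded in awake mice
    during thermal stimulation. Implements motion-artifact scrubbing with
    epoch concatenation, low-pass filtering, polynomial detrending and
    global-component removal; edge-wise static connectivity contrasts with
    animal-level linear mixed models and Benjamini-Hochberg correction;
    dynamic connectivity via per-frame cofluctuation matrices, L1 k-means
    brain-state clustering with Duda-Hart cluster-number selection, and
    occurrence-rate statistics across thermal conditions. Includes a
    Markov-switching synthetic cohort generator with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
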