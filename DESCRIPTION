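Package: remcpm
Title: Connectome-Based Predictive Modeling of REM Sleep from
    Resting-State Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating rapid-eye-movement (REM) sleep to whole-brain
    resting-state functional connectivity. Scores standard polysomnographic
    sleep parameters from 30-second-epoch hypnograms (total sleep time, sleep
    latency, wake after sleep onset, sleep efficiency, stage percentages) with
    early/late-night segmentation for split-night designs; builds Fisher-z
    functional connectivity matrices from node time series; fits
    connectome-based predictive models (CPM) of REM sleep duration with
    per-fold edge selection, leave-one-out cross-validation, and permutation
    significance testing; characterizes the predictive connectome at the
    network-pair, large-scale-network, and regional levels; and compares
    connectome strengths across full-sleep and split-night sleep-deprivation
    groups with one-way ANOVA, multiple-comparison correction, and post-hoc
    contrasts. Includes a synthetic cohort generator (hypnograms, behavior,
    connectivity with planted brain-behavior signal) so the full pipeline can
    be exercised and validated without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
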