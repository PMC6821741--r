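Package: phasic
Title: Pupil Dilation-Event Rate Analysis and EEG Cluster-Based
    Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discriminating neurophysiological responses to two
    classes of brief auditory stimuli from pupillometry and EEG. Implements
    phasic pupil dilation-event detection (positive sign-changes of the
    pupil diameter derivative), causal gamma-kernel event-rate estimation
    with trial normalisation and baseline correction, subject-level
    bootstrap significance testing of condition differences with
    trial-shuffle and control-pool resampling controls, an EEG
    preprocessing chain with summary-statistic epoch rejection, a
    spatio-temporal cluster-based permutation test controlling family-wise
    error, mixed-design ANOVA follow-ups, and a synthetic-data generator
    that emulates the trial structure and signal assumptions of a fast
    passive-listening paradigm so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
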