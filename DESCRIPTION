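Package: dfcstates
Title: Dynamic Functional Connectivity Brain-State Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates dynamic brain states from independent-component
    time courses of resting-state fMRI recordings. Implements time-course
    conditioning (despiking, zero-phase Butterworth band-pass filtering,
    nuisance regression, framewise displacement), sliding-window
    correlations with averaged windows (ASWC) and first-order derivative
    features, exemplar-based cluster-number estimation with the
    Davies-Bouldin and Ray-Turi validity indices, k-means clustering
    under correlation distance, state-dynamics summaries (fraction of
    time, mean dwell time, visits, transitions), group-pooled
    transition-probability models with attractor extraction, and
    permutation-based two-group inference with Benjamini-Hochberg FDR
    control and Hedges' g effect sizes. Includes a Markov-switching
    multivariate-normal cohort simulator so the full pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
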