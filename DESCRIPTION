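Package: actiward
Title: Passive-Movement Correction and Circadian Rhythm Analysis for
    Ward Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing wrist actigraphy recorded from immobile,
    care-dependent patients (e.g. patients with disorders of consciousness).
    Activity recorded in such settings is confounded by passive movements
    imposed by nursing, therapy, transfers and visitors, which themselves
    follow a daily schedule and therefore mimic a circadian rhythm. The
    package implements event-log-driven removal of passive-movement episodes
    with type-specific padding and two-sided median imputation, nonparametric
    circadian indices (interdaily stability, intradaily variability),
    Lomb-Scargle periodogram peak detection with significance filtering,
    day/night activity summaries, rank-based cohort contrasts with effect
    sizes, and a synthetic ward-cohort generator with ground truth so that
    every stage of the pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'actiward-package.R'
    'circadian.R'
    'io.R'
    'cohort.R'
    'stats.R'
    'contrasts.R'
    'correction.R'
    'lombscargle.R'
    'methods-ActivitySeries.R'
    'pipeline.R'
    'simulate.R'
    'summarize.R'
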