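Package: physioclock
Title: Transcriptomic Physiological Age Estimation for Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the physiological (as opposed to chronological) age of a
    biological sample from its gene expression profile. Implements discovery of
    aging-related probes by polyserial correlation of expression with ordinal
    age class calibrated against a randomized-age permutation null, per-probe
    differential-expression calls (one-way ANOVA with Benjamini-Hochberg
    correction, Tukey-HSD post hoc tests and a 1.5-fold-change rule), overlap
    and concordance statistics between probe sets, leave-one-out k-nearest
    neighbour selection of aging classifier probes, and a principal-component
    seeded, AIC-optimised linear age clock that converts a profile into an age
    in days and a percent aging acceleration. Includes cross-batch baseline
    correction using a common technical replicate, quantile normalization,
    lowess-guided noise-floor filtering, and a synthetic-data generator that
    reproduces the statistical structure of a multi-age microarray time course
    so the whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
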