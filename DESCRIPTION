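Package: microstatr
Title: EEG Microstate Analysis with Topographic Clustering and Mixed-Design Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: signal
    preprocessing (resampling, zero-phase band-pass and notch filtering,
    epoching, artifact flagging, spherical-spline channel interpolation,
    average referencing), polarity-invariant Topographic Atomize and
    Agglomerate Hierarchical Clustering (T-AAHC) of global-field-power peak
    maps, sorting of template maps to normative classes A-D, backfitting of
    continuous data, and extraction of microstate parameters (global
    explained variance, duration, frequency, coverage, per-state GFP,
    transition probabilities). Includes a synthetic-cohort generator with a
    hidden semi-Markov state model and spatially smoothed pink noise for
    validation by parameter recovery, a two-group by two-condition mixed
    repeated-measures ANOVA with partial eta squared and retrospective
    observed power, Bonferroni post hoc contrasts, log-transformed Pearson
    correlations, and a minimal European Data Format (EDF) reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
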