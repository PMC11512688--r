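Package: mseeg
Title: Multiscale Entropy Analysis of Infant EEG and Parent Gaze Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for estimating neural signal complexity from
    infant electroencephalography and relating it to parent attention-orienting
    behavior. Reads and writes BrainVision recordings, implements a pediatric
    EEG preprocessing chain (resampling, zero-phase band-pass filtering,
    sinusoidal line-noise regression, epoch extraction, spherical-spline bad
    channel interpolation, sliding-window artifact rejection, average
    re-referencing, and global-field-power-based epoch selection), computes
    modified multiscale sample entropy with a per-scale similarity criterion
    and template counting pooled across discontinuous segments, scores parent
    alternating-gaze duration from coded event logs with two-way random-effects
    intraclass correlation for inter-rater reliability, and fits a general
    linear model of transformed entropy on gaze with influence diagnostics and
    estimated-marginal-means post-hoc contrasts. A synthetic-data generator
    with a ground-truth manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    emmeans,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
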