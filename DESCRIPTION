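Package: fuzzytremor
Title: Takagi-Sugeno Fuzzy Models for Tremor Severity Assessment from
    Wrist-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds interpretable first-order Takagi-Sugeno fuzzy models that
    map wrist-worn smartphone inertial recordings of Essential Tremor patients
    to clinical severity scores (ETRS, QUEST). Provides the full chain: reading
    time-stamped triaxial accelerometer and gyroscope CSV exports, tap-artifact
    trimming and equiripple FIR band-pass filtering of the 7-12 Hz tremor band,
    extraction of time- and wavelet-domain features (signal RMS, signal period,
    Daubechies-8 wavelet-packet dominant frequency and magnitude, power
    growth), spline imputation, CART-wrapper sequential forward feature
    selection, fuzzy c-means clustering driven by fuzzy self-tuning particle
    swarm optimization, Gaussian antecedent and weighted-least-squares
    consequent estimation, and graph-based rule-base simplification by Jaccard
    similarity. A synthetic cohort generator emulates the statistical structure
    of clinical recordings so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    rpart,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
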