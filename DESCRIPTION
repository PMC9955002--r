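Package: seizr
Title: Seizure-Type Detection from Higher-Order Moments of EEG Wavelet
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying epileptic seizure types (tonic-clonic,
    complex partial and electrographic seizures) from short scalp-EEG onset
    segments. Implements windowed higher-order moments (skewness, kurtosis)
    of the temporal, spectral and maximal-overlap discrete wavelet transform
    (MODWT) distributions of 4-second EEG segments; a circular MODWT with
    per-level multiresolution analysis and dyadic band mapping; a
    radial-basis-kernel support vector machine whose box constraint and
    kernel scale are tuned by Gaussian-process Bayesian optimization; class
    rebalancing by random undersampling; stratified k-fold cross-validation;
    and classification metrics including the Matthews correlation
    coefficient. A synthetic EEG generator with three spectrally distinct
    seizure archetypes makes the full pipeline testable without clinical
    recordings. Signals are read from European Data Format (EDF) files or
    delimited text.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    lhs,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
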