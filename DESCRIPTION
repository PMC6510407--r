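Package: gofshrink
Title: Multiscale Image Denoising via Local Goodness-of-Fit Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image denoising for single-channel grayscale images (e.g. MRI)
    by hypothesis testing in the wavelet domain. Local windows of normalized
    wavelet detail coefficients are tested against a reference standard
    Gaussian noise distribution with the Anderson-Darling empirical
    distribution function statistic; coefficients whose window fails to look
    like pure noise are retained verbatim (hard decision), the rest are
    zeroed. Two pipelines are provided: a decimated discrete wavelet
    transform with cycle spinning, and a dual-tree complex wavelet transform
    whose six oriented subbands are tested independently on real and
    imaginary parts. Decision thresholds are calibrated by Monte Carlo so
    that a user-chosen probability of false alarm is met on pure noise.
    Includes the transforms themselves (Daubechies filters by spectral
    factorization, q-shift dual-tree filters by an allpass common-factor
    design), noise-level estimation, threshold calibration machinery,
    synthetic phantoms, metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
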