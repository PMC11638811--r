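Package: alphawaves
Title: Directional Alpha-Band Traveling Wave Analysis for Epoched EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cortical traveling waves along posterior-anterior
    electrode axes in epoched EEG. Each axis is linearly interpolated to seven
    virtual channels, a 500 ms sliding window is moved across every trial, and
    the two-dimensional Fourier power spectrum of each channels-by-time segment
    separates forward (posterior-to-anterior) from backward propagating waves
    by spectral quadrant. Directional power is normalized by the segment's mean
    temporal power at the same frequency and expressed in decibels, then
    averaged over frequency bands (alpha by default) and retention windows.
    Includes a synthetic-EEG generator with controllable plane-wave content and
    1/f background noise for validation, hemisphere-to-contra/ipsilateral role
    mapping for lateralized designs, and a Bayesian inference layer:
    Jeffreys-Zellner-Siow t tests, repeated-measures ANOVA inclusion Bayes
    factors, post hoc comparisons, Bayes-factor linear regression, and Cowan's
    K working-memory capacity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
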