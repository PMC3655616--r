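Package: eegbico
Title: Wavelet Band Power, Bicoherence and Up-Down Threshold Analysis for Rodent EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterising cross-frequency
    structure in multichannel rodent EEG. Provides Morlet wavelet power
    spectra and canonical band powers (delta through gamma), quadratic
    phase coupling via harmonic-wavelet bicoherence with surrogate-based
    significance filtering and a band-pair total-coupling statistic,
    session-comparison statistics (paired/unpaired t, Wilcoxon rank-sum)
    with per-electrode significance masks, planar topographic maps on a
    14-electrode epidural montage, and the up-down (staircase) estimator
    of the 50% mechanical withdrawal threshold from von Frey testing.
    Includes a synthetic-EEG generator with controllable 1/f background,
    band-limited oscillations and phase-coupled triplets so that every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
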