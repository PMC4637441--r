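Package: eegwp
Title: Wavelet-Packet Rhythm Analysis of Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Extraction of the classical EEG rhythm bands (delta, theta,
    alpha, beta) from short multichannel recordings via a four-level
    Daubechies db5 wavelet-packet decomposition, with common average
    re-referencing, wavelet low-pass denoising above 30 Hz, per-channel
    band-energy and energy-ratio features, and descriptive hemispheric,
    task and group contrasts of relative band power. Includes a
    deterministic synthetic EEG generator producing band-limited
    oscillatory recordings with controllable band-energy fractions and
    injected hemispheric, task and training-group effects, so that every
    pipeline stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
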