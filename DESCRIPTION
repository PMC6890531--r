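Package: csibreathe
Title: Respiratory Pattern Sensing from WiFi Channel State Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive respiratory monitoring from C-band channel state
    information (CSI). Implements the full sensing pipeline: a complex
    channel-frequency-response data model with amplitude, phase and
    antenna-pair phase-difference extraction; a scoring-based selection of
    the OFDM subcarrier most sensitive to breathing (variance plus
    envelope-deviation ranks); sym8 wavelet denoising with heuristic SURE
    soft thresholding followed by moving-average smoothing; respiratory-rate
    estimation by STFT spectrogram and by peak counting; spectrogram-based
    apnea detection and sigh detection; and agreement statistics (range
    normalization, mean squared error, Pearson correlation) against a
    contact respiration sensor. A seeded simulator generates ground-truth
    chest-displacement waveforms for normal, Biot's, Cheyne-Stokes, ataxic,
    Kussmaul and sighing breathing patterns and breathing-modulated CSI
    records with heterogeneous subcarrier sensitivity, noise and outlier
    bursts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
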