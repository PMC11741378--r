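Package: avdopt
Title: Haemodynamic Optimisation of Atrioventricular Delay from Pressure
    Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the haemodynamically optimal atrioventricular (AV)
    delay of a dual-chamber pacing system from invasive arterial and central
    venous pressure recordings acquired during protocolised setting changes.
    Provides respiratory baseline removal by asymmetric least squares and by
    maximal-overlap discrete wavelet transform subtraction, beat detection and
    per-beat peak/mean feature extraction, replicate transition-delta
    aggregation, weighted parabolic fitting of the pressure response with
    vertex standard errors (delta method and parametric bootstrap), an
    automated two-test quality-control gate, signal-to-noise and
    agreement statistics (Spearman correlation, Bland-Altman), and a
    synthetic paced-haemodynamics generator with ground truth so the whole
    pipeline is verifiable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    data.table,
    pracma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
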