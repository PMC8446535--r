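Package: kv3noise
Title: Synaptic Noise, Spike Synchrony, and Presynaptic Calcium Analysis
    for Kv3 Channel Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis toolchain for studies of presynaptic Kv3 potassium
    channel modulation of synaptic noise in auditory brainstem circuits.
    Provides Morlet-wavelet band decomposition of membrane potential
    recordings and Ornstein-Uhlenbeck wavelet-filtered noise stimulus
    synthesis; extracellular spike detection with median-absolute-deviation
    thresholding and spike-triggered averaging; the jitter-based synchrony
    index (JBSI) with a brute-force validation oracle; a Hodgkin-Huxley
    point-membrane simulator with a high-voltage-activated Kv3 conductance
    and pulse-train stimulus calibration; fluorescence puncta analysis
    (bleach correction, F/F0, segmentation, responding classification, Hill
    fits); Manders and object-based co-localization; Boltzmann conductance
    fits, Fisher-z correlation averaging, Holm correction and paired
    equivalence testing; plus seeded synthetic-data generators with ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    minpack.lm,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
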