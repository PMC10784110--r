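Package: mclfp
Title: Simulation and Mitigation of Mismatch Compression in Differential LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A layered simulator of differential local field potential (dLFP)
    recordings from sensing-enabled deep-brain-stimulation devices, modelling
    impedance-mismatch-dependent stimulation-artifact leakage, amplifier gain
    compression (linear, hard-clipping and tanh soft-clipping stages) and
    undersampling by the onboard ADC; together with the frequency-domain
    analysis chain those devices require: Welch log-power spectral densities
    with a Blackman-Harris window, analytic forecasting of stimulation shaping
    harmonics and their aliases, fourth-order polynomial baseline removal,
    artifact-avoiding adjusted oscillatory bands with median aggregation, and
    the gain compression ratio (GCr) and over-range-marker diagnostics used to
    grade compression severity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
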