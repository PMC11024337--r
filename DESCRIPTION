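Package: thetatrain
Title: Simulation and Analysis of Rhythmic TMS-EEG Working-Memory Training Studies
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyze combined rhythmic transcranial
    magnetic stimulation (rhTMS) and auditory working-memory training
    experiments with concurrent EEG. Provides a synthetic-data generator
    (task protocols, 5 Hz TMS pulse trains, equal-variance Gaussian observer
    behavior, multichannel 1/f EEG epochs with theta bursts and TMS
    artifacts), BrainVision file input/output, a TMS-artifact removal and
    preprocessing chain, Morlet wavelet time-frequency and theta-band
    Hilbert-envelope analysis with baseline z-scoring, sensor-space
    cluster-based permutation statistics, power-behavior correlation maps,
    and signal-detection/learning-slope behavioral statistics with effect
    size and sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
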