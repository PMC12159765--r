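Package: tinnpac
Title: Source-Level EEG Phase-Amplitude Coupling Analysis for Tinnitus Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for resting-state EEG cross-frequency
    coupling analysis in tinnitus research. Provides preprocessing
    (band-pass/notch filtering, resampling, epoching, amplitude-based epoch
    rejection), minimum-norm source inversion with AAL region-of-interest
    aggregation, Kullback-Leibler modulation-index phase-amplitude coupling
    (comodulograms and band-averaged theta-beta / theta-gamma PAC),
    spectral power and amplitude-amplitude coupling, phase-synchronization
    connectivity (coherence, PLV, PLI, wPLI), mixed-design ROI-by-Group
    statistics with bootstrap post-hoc tests and FDR correction, and a
    Fisher-discriminant + k-nearest-neighbour classifier with leave-one-out
    cross-validation. A synthetic-cohort generator with planted coupling
    structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    class,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
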