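Package: epierp
Title: Spatio-Temporal Event-Related Potential Analysis for Mouse Epidural EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization of auditory event-related potentials (ERPs)
    recorded from multi-channel epidural EEG in mice, and genotype
    classification from single-trial spatio-temporal ERP features.
    Provides stimulus-locked epoching with amplitude-based artifact
    rejection, trial block averaging, N1/P1/N2 peak feature extraction,
    principal-component waveform features, Fisher linear discriminant
    classification with leave-one-animal-out cross-validation and nested
    selection of the number of components, projection-plane geometry for
    waveform clusters, rank-one factorization of the discriminant into a
    temporal profile and per-channel spatial weights, and interpolated
    cortical maps of discriminant projections. Includes a synthetic-cohort
    generator with planted genotype effects, pink background noise and
    artifact spikes, plus EDF/TSV/JSON readers and writers for recordings,
    events, montages and cohort manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
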