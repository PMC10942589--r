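Package: modwave
Title: Discriminating Traveling Waves from Sequentially Activated Neural Modules
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for deciding whether wave-like spatiotemporal
    patterns in neural recordings reflect genuinely traveling waves or the
    sequential activation of discrete, spatially fixed modules. Provides an
    analytic model of two sequentially activated Gaussian sources with
    closed-form concavity, unimodality and peak-velocity laws; a ground-truthed
    synthetic multi-electrode-array (MEA) generator producing local field
    potentials with modular, phase-locked spiking; zero-phase filtering,
    analytic-signal phase and amplitude-thresholded phase-crossing detection;
    spatiotemporal flood-fill wave detection with phase-latency maps,
    phase-latency-distance correlation (PLDC), wave-center paths and speed
    estimates; average local spiking activity (ALSA) and first-spike onset
    extraction; and Hartigan's dip statistic with a uniform-null bootstrap for
    quantifying the modularity of onset-time distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    data.table,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
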