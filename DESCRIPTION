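Package: arousalnet
Title: Metastable Clustered Spiking Networks and Arousal-Modulated Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates clustered and uniform excitatory/inhibitory networks
    of leaky integrate-and-fire neurons with exponential synapses, in which
    arousal is modeled as a modulation of the mean or heterogeneity of
    background external input. Provides the accompanying analysis stack:
    mean-field theory for the self-consistent population rates (with and
    without quenched input disorder), an effective two-cluster reduction
    with flow maps, potentials and barrier heights, population decoding of
    stimulus identity with cross-validated linear discriminants and shuffle
    nulls, single-cell discriminability, cluster activation statistics,
    rate-normalized multitaper spike spectra, Fano factors, and a synthetic
    extracellular-session generator with pupil preprocessing, unit quality
    control, tone-responsiveness testing and pupil-binned analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
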