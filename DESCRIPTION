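Package: pfcdyn
Title: Single-Trial Decision Dynamics from Prefrontal Field Potentials and Spikes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers a single-trial index of prefrontal decision dynamics
    from evoked field potentials by principal components analysis of
    trial-stacked waveforms, and relates that index to task variables and
    single-unit firing through sliding-window regression with the
    coefficient of partial determination (CPD), noise-component and
    orthogonalisation controls, cross-regional effort/delay models, and
    sign-flip permutation tests. Ships a seeded synthetic-data generator
    emulating value-guided choice sessions (trial tables, evoked LFPs,
    spike rasters, multi-subject virtual electrodes), and a spiking
    winner-take-all attractor network of choice whose summed activity is
    analysed with the same pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
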