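Package: neurostates
Title: Latent Brain-State Dynamics from Parcellated fMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and characterization of discrete latent brain states
    from parcellated fMRI time series. Fits Gaussian-emission hidden Markov
    models (expectation-maximization with k-means initialization, Viterbi
    decoding, leave-one-subject-out Calinski-Harabasz model selection) and
    computes the downstream state statistics used in naturalistic-imaging
    studies: fractional occupancy, dwell times, transition matrices,
    intersubject state-sequence synchrony, edge-level cofluctuation aligned to
    state transitions, diffusion-map connectivity gradients with state
    projections, event-boundary-aligned state occurrence, and attention-state
    coupling. All inference is permutation-based, built on circular-shift
    surrogates with Benjamini-Hochberg correction. Includes a synthetic-data
    generator with known ground truth for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
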