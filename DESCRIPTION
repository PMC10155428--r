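Package: synergykit
Title: Muscle Synergy, Complexity and Spinal Motor-Output Analysis of Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel surface electromyography (sEMG)
    recorded during brain motor control assessment (BMCA) sessions. Implements
    Butterworth band-pass and median-filter preprocessing, RMS enveloping with
    trial segmentation and time normalization, Higuchi fractal dimension
    estimation of envelope complexity, rostro-caudal spinal motor-output maps
    from a configurable myotomal chart, muscle synergy extraction by
    non-negative matrix factorization with variance-accounted-for model-order
    selection, cross-participant synergy matching by cosine similarity, and a
    nonparametric group-statistics battery (Lilliefors normality, Wilcoxon
    signed-rank, Mann-Whitney U, Bonferroni correction, TOST equivalence).
    Includes a protocol-faithful synthetic session generator with planted
    synergy structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    nortest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
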