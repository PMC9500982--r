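Package: eegcube
Title: 3D Spatiotemporal EEG Representations and Channel-Bottleneck 3D CNNs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts multichannel EEG trials into 3D spatiotemporal tensors
    (electrode-to-grid topographic mapping, thin-plate-spline interpolation of
    empty grid cells, bicubic upsampling, temporal stacking of 1-s windows) and
    provides declarative 3D convolutional network architectures for binary
    valence/arousal classification: a channel-bottleneck CNN together with plain
    C3D-style and LSTM baselines. Includes exact trainable-parameter and FLOP
    accounting with pairwise reduction reports, a seeded SGD training and
    repeated-evaluation harness with confusion-matrix metrics, and a synthetic
    generator of DEAP-structured EEG with controllable class-conditional
    band-power effects for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
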