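Package: channelgan
Title: GAN Synthesis and Validation of Annotated Single-Channel Patch-Clamp Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to synthesize fully annotated single ion-channel patch-clamp
    records with a deep convolutional generative adversarial network trained on
    paired (raw current, idealization) time series, and to validate the synthetic
    data quantitatively. Includes a continuous-time Markov gating simulator with
    filtered Gaussian noise as the traditional-method baseline, robust scaling and
    windowing preprocessing, unbiased Gaussian-kernel maximum mean discrepancy,
    exact and approximate dynamic time warping, all-points amplitude histograms,
    dwell-time exponential-mixture kinetics, and a manifold embedding with a
    permutation cluster-separation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
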