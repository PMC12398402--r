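Package: tvrnn
Title: Time-Varying Recurrent Neural Networks for Early Classification of
    Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential binary classification of trial-structured multi-channel
    neural time series with recurrent networks whose input, recurrent and
    output weights switch across temporal windows (time-varying RNNs), trained
    end-to-end by backpropagation through time. Includes standard RNN training
    strategies (final-step and all-step cross-entropy losses), a causal
    transformer baseline, sliding-window RNN and SVM baselines, temporal
    decoding metrics (per-time-point cross-validated accuracy, area under the
    accuracy curve above chance, earliest decoding time with one-tailed tests
    and Benjamini-Hochberg correction), integrated-gradient SHAP-style
    channel-by-time attribution, gradient-stability diagnostics based on
    recurrent Jacobian product norms, and a chirp-signal trial simulator with
    time-shuffled controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    signal,
    pracma,
    rhdf5,
    RcppTOML,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
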