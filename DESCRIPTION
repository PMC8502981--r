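Package: beatcast
Title: Forecasting Irregular Cardiac Action Potentials with Reservoir
    Computing and Gated Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates irregular cardiac action-potential time series from
    mechanistic ionic cell models (Fenton-Karma paced with random cycle
    lengths, Noble 1962 driven by a time-rescaled chaotic Lorenz system,
    and a Corrado-Niederer variant of the Mitchell-Schaeffer model),
    prepares them for sequence learning by voltage-adaptive resampling and
    beat-aligned train/test splitting, and trains five recurrent
    forecasters (LSTM, GRU, echo state network, clustered echo state
    network, and a physics-informed hybrid echo state network) for
    closed-loop multi-beat voltage prediction. Evaluation covers root mean
    square error on the resampled test grid and per-beat action-potential
    duration errors, with seed-averaged grid search and cross-method
    comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
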