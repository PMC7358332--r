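Package: slowgc
Title: Instantaneous and Directed Granger-Geweke Connectivity from Slowly
    Sampled Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates conditional Granger-Geweke functional connectivity
    (instantaneous iGC, directed dGC, the full linear-dependence measure,
    and partial correlations) from multi-region time series sampled at slow
    rates such as fMRI repetition times, with segment-aware multivariate
    autoregressive fitting, stationarity and model-adequacy diagnostics,
    motion scrubbing, and subsampling utilities. Includes a vector
    Ornstein-Uhlenbeck network simulator with exact discretization,
    hemodynamic-response convolution and emergent-timescale analysis that
    explains when lag-based connectivity is recoverable at slow sampling;
    ZCA and generalized-eigenvector decorrelation; linear-classifier
    pipelines with permutation testing; two-level recursive feature
    elimination with elbow detection; phase-scrambling surrogates and
    digraph extraction; and leave-one-out prediction of individual scores
    from connectivity features with robust correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
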