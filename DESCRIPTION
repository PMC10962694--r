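Package: cdrnn
Title: Continuous-Time Deconvolutional Regressive Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distributional regression for variably-spaced event streams in
    which a small feedforward neural network plays the role of a
    continuous-time impulse response function: the history of timestamped
    predictors is convolved with network-derived weights to parameterize every
    parameter of the response distribution (location and scale of a normal by
    default), relaxing discrete-time, linearity, stationarity and
    homoscedasticity assumptions while remaining interpretable. Includes mixed
    random effects, Monte Carlo dropout uncertainty, perturbation-based effect
    queries (impulse response curves and surfaces, functional-form slices,
    interaction surfaces, scale-parameter responses, nonstationarity curves),
    constraint-defined null models, ensembling, paired permutation tests on
    out-of-sample log likelihood, exclusion filters and partitioning schemes
    for reading-time and imaging-style data, and a synthetic ground-truth
    generator with known convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
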