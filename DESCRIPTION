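Package: stimpredict
Title: Prediction and Short-Term Memory in Stimulated Neuronal Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Information-theoretic analysis of stimulus prediction by
    multielectrode-array (MEA) recordings of cultured cortical networks.
    Provides a correlated-interval hidden-Markov stimulus generator, a
    synthetic 59-electrode MEA simulator with stimulus-evoked network
    responses and a mechanistic cascade model, binary-word rasterisation
    with response masking, plug-in and Bayesian (Dirichlet-mixture)
    entropy and mutual-information estimators for binary words,
    time-shifted mutual-information curves quantifying prediction and
    short-term memory, and a predictive information-bottleneck analysis
    of memory-prediction efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
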