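Package: changenet
Title: Synaptic Depression and Persistent-Activity Network Models of Visual
    Change Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the go/no-go visual change-detection task used in mouse
    two-photon visual-behavior experiments, trains small neural network models
    that solve it using either short-term synaptic depression (Tsodyks-Markram
    resource dynamics on the input synapses), persistent recurrent activity, or
    both, and provides the behavioral and neural analysis battery that
    discriminates the two short-term-memory mechanisms: response-probability
    matrix symmetry, change modulation indices, linear population decoding,
    PCA repeat-distance curves, and stimulus-omission probes. Includes a
    synthetic-data module that generates task sessions, sparse non-negative
    image embeddings, and adapting neural populations with known ground truth
    for validating the metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
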