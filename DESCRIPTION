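Package: m6AmStack
Title: Stacking Ensemble Deep Learning for m6Am Site Prediction in RNA
Version: 0.1.0
Authors@R:
    person("m6AmStack", "Maintainers", email = "maintainers@m6amstack.org",
           role = c("aut", "cre"))
Description: Identifies N6,2'-O-dimethyladenosine (m6Am) sites in 41-nt RNA
    windows centered on a candidate adenosine. Three heterogeneous
    convolutional/recurrent base classifiers (a densely connected network with
    squeeze-and-excitation attention, a dilated convolutional network with a
    bidirectional LSTM, and a multi-scale residual network with a bidirectional
    GRU) are trained on one-hot encoded windows; their out-of-fold
    probabilities, concatenated with the flattened one-hot features, feed a
    ridge-penalized logistic-regression meta-learner. Ships sequence I/O and
    window extraction, one-hot / nucleotide-chemical-property / nucleotide-
    density encoders, threshold and ranking evaluation metrics with repeated
    stratified cross-validation, positional nucleotide enrichment analysis, a
    planted-motif synthetic data generator, and a command-line interface, so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
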