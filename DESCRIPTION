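Package: repalign
Title: Sparse Non-Negative Embeddings from Triplet Odd-One-Out Behaviour and
    Representational Alignment Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns interpretable, sparse, non-negative object embeddings from
    triplet odd-one-out similarity judgements by mean-field variational
    inference under a spike-and-slab prior (the SPoSE/VICE family of models),
    and compares two such embeddings dimension-by-dimension to localize
    representational alignment and misalignment. Includes simulation of
    odd-one-out choices from arbitrary feature matrices, split-half
    reliability across training runs, ridge-regression mapping from features
    to embedding dimensions, representational similarity analysis based on
    context-averaged triplet choice probabilities, jackknife dimension
    relevance for individual choices, and a synthetic-data generator for
    end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
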