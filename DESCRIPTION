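Package: milsocnet
Title: Multiple-Instance Attention Networks for Depression Signals in
    Microblog Timelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Weakly supervised detection of depressed users from bags of
    short social-media posts. Implements hierarchical multiple-instance
    learning networks (MIL-SocNet and its anaphora-aware extension
    MILA-SocNet) built from bidirectional GRU encoders with word- and
    post-level attention, trained from user-level labels only, so that
    post-level (instance) labels are recovered as a by-product. Includes
    a synthetic microblog corpus generator with known instance-level
    ground truth, text normalisation and bag encoding, GloVe-format
    word-vector loading, an open pronoun-category lexicon standing in
    for proprietary LIWC features, and the evaluation protocol:
    chunked stratified holdout cross-validation, classification metrics,
    ROC/AUC, log-likelihood, and small-sample corrected AIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
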