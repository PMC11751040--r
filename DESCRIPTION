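Package: bwenet
Title: Centered-Residue PTM Site Prediction with Binary-Weight Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-translational modification of the residue at the
    center of a fixed-length peptide window, with cysteine
    S-carboxyethylation on 41-mers as the motivating case. Features are
    built by Binary-Weight Encoding, a one-hot representation whose rows
    are scaled by an exponentially decaying positional weight, and
    classified by a 1-D CNN, a bidirectional LSTM, additive (Bahdanau)
    attention and a fully connected head implemented natively with
    'RcppArmadillo'. Includes comparison encoders (EAAC, DPC, TPC, CTD),
    grouped cross-validation with Sn/Sp/ACC/MCC/AUROC/AUPR, Mann-Whitney
    model comparison, a synthetic window generator with a tunable
    center-concentrated signal, and a dynamic-time-warping comparison of
    learned attention profiles against the positional weight curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    withr,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    e1071,
    xgboost,
    optparse
Config/testthat/edition: 3
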