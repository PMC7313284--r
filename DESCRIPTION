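Package: actiseq
Title: Hybrid Weighted-SVM/Hidden-Markov Classification of Activity Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Recognizes human activities from time-ordered windows of wearable
    sensor features by combining a class-cost-weighted Gaussian-kernel support
    vector machine with a supervised hidden Markov model. Features are scaled
    to [-1, 1], reduced by principal component analysis, classified frame by
    frame with a one-vs-one weighted SVM whose per-class costs counter class
    imbalance, and the resulting label stream is temporally smoothed by
    Viterbi decoding of an HMM whose emissions combine the principal-component
    scores with the SVM label estimates. Includes stratified cross-validation
    for hyperparameter selection and out-of-fold label estimation,
    macro-averaged evaluation metrics with confusion matrices, a synthetic
    sequence generator with Markov dynamics and configurable class imbalance,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
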