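Package: lspforest
Title: Interpretable Classification of Health-Forum Sentences with
    Labeled Sequential Patterns and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies sentences from online health forums into medication,
    symptom and background classes, and explains the predictions. Sentences
    are mapped to tag sequences (part-of-speech tags plus lexicon-driven
    DRUG, SYMP and FREQ tags), frequent labeled sequential patterns are
    mined under a maximum-gap constraint and used, together with
    semantic-type, word-based, morphological and thread-heuristic features,
    as an interpretable feature space. A random forest classifier is
    decomposed into per-feature contribution vectors, and low-impurity
    decision paths are forward-selected into compact discriminative
    patterns. Includes a synthetic corpus generator with planted patterns
    for end-to-end validation, plus SVM and lasso baselines and weighted
    cross-validated evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    ranger,
    e1071,
    glmnet,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
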