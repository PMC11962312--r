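Package: weakner
Title: Weakly Supervised Named Entity Recognition from Synthetic Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building named entity recognition (NER) training data
    from synthetic clinical-style text annotated by large language models.
    Provides penalized longest-common-subsequence originality scoring to
    detect training-data leakage in generated corpora, prompt construction
    and JSON annotation-response parsing, alignment of reported entity
    surfaces to character spans and IOB2 token tags, entity-level
    precision/recall/F1 evaluation with Wilson score confidence intervals,
    a seeded synthetic-corpus generator with gold annotations and mock
    annotators with a configurable noise model, a dictionary (gazetteer)
    downstream tagger, and learning-curve and prompt-comparison experiment
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
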