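Package: epiwatch
Title: Screening of False Epidemic Information and Early Warning of
    Public Opinion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage surveillance of online epidemic information. Stage
    one identifies and filters false epidemic messages: reliable web
    sources are selected by link analysis on a column-stochastic transfer
    matrix, nine features spanning subject relevance (pointwise mutual
    information), text structure, emotional polarity and publisher
    behaviour are extracted per message, and a second-order
    gradient-boosted decision-tree classifier (implemented from first
    principles) separates true from false items, with a regulatory
    publisher-history feature driving threshold elimination. Stage two
    computes a five-indicator public-opinion early-warning series over
    daily message windows: quantity change rate, regional coverage,
    emotional tendency, subject concentration via adaptive PMI
    clustering, and new-subject detection. A seeded synthetic-corpus
    generator emulates the statistical structure of crawled epidemic
    message data so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
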