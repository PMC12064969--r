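Package: soclisten
Title: Social-Listening Screening and Descriptive Analysis of Drug-Cessation Narratives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for social-listening pharmacovigilance
    studies of Reddit-style corpora: ingestion and normalization of Pushshift
    JSON Lines records, inclusion screening by fuzzy drug-name keywords
    (Levenshtein variants), subreddit context, cessation keywords and a date
    window, salted one-way identifier obfuscation and PII redaction, seeded
    random sampling, codebook-based annotation validation, and the descriptive
    statistics of the screened corpus (construct prevalences, per-author
    activity, dose-sequence distributions). Includes a synthetic-corpus
    generator with planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    generics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
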