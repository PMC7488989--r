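Package: comention
Title: Co-Mention Mining, Association Scoring and Trend Analysis for
    Literature Abstract Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tags typed entity dictionaries in abstract corpora
    (MEDLINE/PubMed XML or a JSONL dialect), scores pairwise entity
    associations with a weighted abstract/sentence co-occurrence count and
    a marginally normalized s-score, estimates empirical significance
    (z-score, one-sided p) against sampled negative sets, measures
    per-entity publication-trend strength with the tie-corrected
    Mann-Kendall test, evaluates boolean entity/keyword queries with
    digest filtering and sorting, exports associative networks and digest
    tables as JSON/CSV, and reproduces a ROC/AUC accuracy-assessment
    protocol. Ships a seeded synthetic-corpus generator with known ground
    truth (planted associated pairs and monotone trends) so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
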