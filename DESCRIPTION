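Package: hedgedev
Title: Development and Validation of Boolean Literature-Search Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating Boolean search filters
    ("hedges") against labeled bibliographic corpora. Parses MEDLINE
    flat files, evaluates PubMed-style Boolean queries with field tags
    ([tw], [TIAB], [ti], [MeSH], [sh], [pt]), computes retrieval metrics
    (recall, precision, F-measure, fallout, number needed to read),
    screens candidate single-term filters and exhaustively scores their
    OR-combinations, induces multi-term filters by recursive partitioning
    with cost-weighted error rates and chi-square significance stopping,
    and quantifies the recall gained by checking reference lists of
    retrieved articles. Includes a seeded generator of synthetic
    low-prevalence labeled corpora for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
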