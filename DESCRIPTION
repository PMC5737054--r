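Package: meshquery
Title: MeSH Query Expansion and BM25 Retrieval for Dataset Metadata Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for ranked retrieval of biomedical
    dataset metadata. Indexes JSON metadata records as flattened full-text
    documents, expands queries with synonyms from a local MeSH-style
    controlled-vocabulary table (with a configurable per-token term cap and
    clause weighting), ranks with BM25, writes TREC-format run files, and
    evaluates runs against graded relevance judgments with the standard and
    inferred metrics (P@10 with and without partial relevance, NDCG@10,
    infAP, infNDCG over stratified-sampled qrels). Includes a seeded
    synthetic test-collection generator with tunable vocabulary mismatch, a
    terms-by-weights parameter sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringi,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
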