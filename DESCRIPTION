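Package: phenorbp
Title: Phenotype-Driven Disease Ranking with RelativeBestPair and Classical
    Ontology Similarity Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate hereditary diseases from a set of query phenotype
    terms drawn from an HPO-like ontology. Implements the RelativeBestPair
    score, which caps each query term's per-disease contribution at a
    threshold alpha, together with seven classical information-content and
    graph-based term-similarity measures (Resnik, Lin, Jiang-Conrath,
    Relevance, information coefficient, graph IC, Wang) combined by a
    one-sided best-match set similarity. Includes an OBO flat-file parser,
    an annotation indexer with true-path propagation, a patient simulator
    with noise and imprecision corruptions, synthetic fixture generators,
    and a top-k / cumulative-rank benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
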