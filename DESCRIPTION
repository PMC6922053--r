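Package: conceptCooc
Title: Medical Concept Embeddings from Multimodal Co-Occurrence Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds concept-concept co-occurrence matrices from
    concept-normalized clinical text and from timestamped patient event
    streams (claims- and notes-style data), factorizes them into dense
    concept embeddings via shifted positive pointwise mutual information
    (SPPMI) plus truncated SVD, a GloVe-style weighted least-squares fit,
    or raw-count SVD, and evaluates any embedding set with a
    category-matched bootstrap statistical-power benchmark and Spearman
    correlation against human similarity judgements. Includes a synthetic
    data generator with planted related concept pairs so the whole
    pipeline is testable without access to licensed vocabularies or
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
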