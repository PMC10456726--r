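Package: metacurate
Title: Controlled-Vocabulary Standardization of Sample Metadata Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Standardizes freetext sample-metadata matrices against orthogonal
    controlled vocabularies built from ontology subsets. A character-trigram
    tf-idf vector space with cosine-similarity nearest-neighbor matching,
    synonym mapping and substring rescue converts user-submitted strings into
    canonical main terms in three passes; terms that cannot be matched are
    adopted into the vocabulary after confirmation and the matching models are
    refit, so every controlled cell of a standardized matrix is guaranteed to
    be a vocabulary term queryable by string equality. Includes readers for
    taxdump-style and tree-number-style ontology dumps, subtree extraction with
    a closed set of exclusion filters, TSV/CSV/JSON persistence, a programmatic
    query interface over stored studies, and seeded synthetic fixtures
    (vocabularies, typo corpora, ontology dumps, a worked-example matrix) so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'normalize.R'
    'AllClasses.R'
    'categories.R'
    'vocabulary.R'
    'vocab-io.R'
    'ontology.R'
    'matcher.R'
    'matrix-io.R'
    'standardize.R'
    'service.R'
    'fixtures.R'
    'worked-example.R'
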