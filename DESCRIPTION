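Package: pcgo
Title: Protein Complex Function Annotation with Gene Ontology Terms from
    Literature Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hybrid framework for annotating the function of protein
    complexes with Gene Ontology (GO) terms. A character-bigram subword
    skip-gram embedding is trained on (or loaded for) a biomedical text
    corpus; complex and GO-term names are composed into unit-norm query
    vectors; per-namespace GO sub-embeddings are indexed in an exact k-d
    tree for cosine nearest-neighbour retrieval; random-forest, logistic
    regression and naive Bayes classifiers are trained on positive and
    sampled-negative complex-GO pairs and evaluated by complex-level
    leave-one-out cross-validation; the supervised and nearest-neighbour
    prediction lists are consolidated with a hypergeometric child-term
    enrichment test; and predictions are benchmarked against independent
    annotation tables via Wang semantic similarity, coverage statistics
    and subunit-overlap filtering. Deterministic synthetic fixtures
    (toy ontologies, complex tables, corpora and planted embeddings)
    support end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    e1071,
    glmnet,
    pROC,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
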