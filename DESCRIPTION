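Package: biofacet
Title: Faceted Search and Event Annotation over Biomedical Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates biomedical abstracts with dictionary-based entity
    mentions (genes, chemicals, diseases) and nine-class biomolecular event
    types, using TF-IDF sentence classifiers (multinomial naive Bayes,
    semi-supervised naive Bayes with EM, maximum entropy) and a linear-chain
    conditional random field that tags event-trigger phrases with BIO labels.
    Serves the annotated collection through an in-memory faceted full-text
    index with conjunctive query refinement, facet-count tag clouds and
    prefix autocomplete. Includes exact and soft trigger-boundary evaluation
    and a deterministic synthetic-corpus generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
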