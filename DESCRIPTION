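Package: icukg
Title: ICU Readmission Prediction with Ontology-Based Knowledge Graph
    Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting 30-day intensive-care-unit
    (ICU) readmission from electronic health record (EHR) style tables.
    Clinical terms and codes are semantically annotated against biomedical
    ontologies (lexical retrieval with Levenshtein selection for free text,
    direct code lookup for coded vocabularies), the annotations are assembled
    into a patient knowledge graph, and knowledge-graph embeddings (random-walk
    skip-gram, translational TransE, and axiom-corpus embeddings) are
    aggregated into per-stay vectors for classical classifiers under
    cross-validation. A synthetic cohort and toy-ontology generator with a
    planted, ontology-mediated readmission signal makes every stage runnable
    and testable without access-controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
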