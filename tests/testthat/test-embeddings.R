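chain_kg <- function() {
  ids <- c("a", "b", "c")
  ont <- toy_ontology("CH", ids, stats::setNames(c("la", "lb", "lc"), ids),
                      subclass_edges = data.frame(child = c("a", "b"),
                                                  parent = c("b", "c")))
  build_kg(list(ont))
}

test_that("walk generation enumerates, caps and validates", {
  kg <- chain_kg()
  # chain a -> b -> c at depth 2, prefix-inclusive
  ws <- generate_walks(kg, "a", max_depth = 2)
  expect_equal(ws$walks,
               list("a", c("a", "subClassOf", "b"),
                    c("a", "subClassOf", "b", "subClassOf", "c")))
  expect_equal(ws$mode, "exhaustive")

  # isolated vertex: the lone root walk
  ids <- "I:C1"
  iso <- build_kg(list(toy_ontology("I", ids, stats::setNames("iso", ids))))
  expect_equal(generate_walks(iso, "I:C1")$walks, list("I:C1"))

  # full mode keeps only maximal walks
  wf <- generate_walks(kg, "a", max_depth = 2, mode = "full")
  expect_equal(wf$walks, list(c("a", "subClassOf", "b", "subClassOf", "c")))

  # relation tokens can be dropped
  wv <- generate_walks(kg, "a", max_depth = 2, include_relations = FALSE)
  expect_equal(wv$walks[[3]], c("a", "b", "c"))

  # star with 600 leaves: sampling cap at 500, deterministic under seed
  leaves <- sprintf("S:L%03d", 1:600)
  ids <- c("S:HUB", leaves)
  star <- toy_ontology("S", ids, stats::setNames(paste("n", ids), ids),
                       subclass_edges = data.frame(child = leaves,
                                                   parent = "S:HUB"))
  # walk from hub downward requires reversed edges; root at leaves goes up,
  # so flip: make hub the child side by walking bidirectionally
  wsamp <- generate_walks(build_kg(list(star)), "S:HUB", max_depth = 1,
                          max_walks = 500, seed = 3, bidirectional = TRUE,
                          mode = "full")
  expect_length(wsamp$walks, 500)
  expect_equal(wsamp$mode, "sampled")
  wsamp2 <- generate_walks(build_kg(list(star)), "S:HUB", max_depth = 1,
                           max_walks = 500, seed = 3, bidirectional = TRUE,
                           mode = "full")
  expect_identical(wsamp$walks, wsamp2$walks)

  expect_error(generate_walks(kg, "nope"), "root not in the KG")
})

test_that("emitted walks match exhaustive path enumeration on random DAGs", {
  for (seed in 1:6) {
    n <- sample(5:50, 1)
    kg <- random_dag_kg(n, seed = seed)
    triples <- rbind(kg$class_edges, kg$annotation_edges)
    roots <- c(sample(kg$class_vertices, 3), kg$instance_vertices[1])
    for (root in roots) {
      got <- generate_walks(kg, root, max_depth = 4, max_walks = 1e6)$walks
      want <- paths_oracle(triples, root, 4, prefix = TRUE)
      expect_setequal(vapply(got, paste, "", collapse = "|"),
                      vapply(want, paste, "", collapse = "|"))
    }
  }
})

test_that("random-walk training covers every vertex at the requested width", {
  kg <- chain_kg()
  sp <- train_rdf2vec(kg, dimension = 2, epochs = 2, seed = 1)
  expect_equal(sp$dimension, 2)
  expect_true(all(c("a", "b", "c") %in% rownames(sp$vectors)))

  kg16 <- random_dag_kg(20, 4)
  sp16 <- train_rdf2vec(kg16, dimension = 16, seed = 5)
  expect_true(all(c(kg16$class_vertices, kg16$instance_vertices) %in%
                    rownames(sp16$vectors)))
  expect_true(all(rowSums(is.finite(sp16$vectors)) == 16))

  expect_error(train_rdf2vec(kg, dimension = 0), "dimension")

  a <- train_rdf2vec(kg, dimension = 8, seed = 9)
  b <- train_rdf2vec(kg, dimension = 8, seed = 9)
  expect_identical(a$vectors, b$vectors)
})

test_that("all three methods separate a two-cluster KG in cosine space", {
  a <- generate_toy_ontology("CLA", 12, 2, 0, seed = 1)
  b <- generate_toy_ontology("CLB", 12, 2, 0, seed = 2)
  kg <- build_kg(list(a, b))
  kg_lab <- build_kg(list(a, b), include_labels = TRUE)
  sep <- function(space) {
    M <- space$vectors[c(a$classes, b$classes), ]
    Mn <- M / sqrt(rowSums(M^2))
    S <- tcrossprod(Mn)
    ia <- seq_along(a$classes); ib <- length(a$classes) + seq_along(b$classes)
    intra <- mean(c(S[ia, ia][upper.tri(S[ia, ia])],
                    S[ib, ib][upper.tri(S[ib, ib])]))
    intra - mean(S[ia, ib])
  }
  expect_gt(sep(train_rdf2vec(kg, dimension = 32, epochs = 100, seed = 3)), 0)
  expect_gt(sep(train_opa2vec(kg_lab, dimension = 32, epochs = 150,
                              seed = 3)), 0)
  expect_gt(sep(train_transe(kg, dimension = 32, epochs = 200, seed = 3)), 0)
})

test_that("translational scoring follows the h + r - t geometry", {
  expect_equal(transe_score(c(1, 0), c(0, 1), c(1, 1)), 0)
  expect_equal(transe_score(c(2, 3), c(0, 0), c(2, 3)), 0)
  expect_equal(transe_score(c(0, 0), c(0, 0), c(3, 4), norm = "L2"), 5)
  expect_equal(transe_score(c(0, 0), c(0, 0), c(3, 4), norm = "L1"), 7)
  expect_error(transe_score(c(1, 0), c(0, 1, 2), c(1, 1)), "mismatch")
})

test_that("TransE ranks true triples above corrupted ones after training", {
  kg <- random_dag_kg(15, seed = 8)  # ~20 triples
  triples <- rbind(kg$class_edges, kg$annotation_edges)
  sp <- train_transe(kg, dimension = 32, epochs = 200, seed = 2)
  score <- function(h, r, t) transe_score(sp$vectors[h, ], sp$vectors[r, ],
                                          sp$vectors[t, ])
  true_mean <- mean(mapply(score, triples$subject, triples$predicate,
                           triples$object))
  set.seed(4)
  ents <- sp$meta$entities
  corr_mean <- mean(mapply(score, triples$subject, triples$predicate,
                           sample(ents, nrow(triples), replace = TRUE)))
  expect_lt(true_mean, corr_mean)

  # entity vectors end every epoch on the unit sphere
  E <- sp$vectors[sp$meta$entities, ]
  expect_lt(max(abs(sqrt(rowSums(E^2)) - 1)), 1e-6)

  s2 <- train_transe(kg, dimension = 32, epochs = 200, seed = 2)
  expect_identical(sp$vectors, s2$vectors)
  expect_error(train_transe(kg, margin = 0), "margin")
})

test_that("axiom corpus verbalizes asserted, inferred and lexical triples", {
  ids <- c("a", "b", "c")
  ont <- toy_ontology("AX", ids,
                      stats::setNames(c("heart disease", "lb", "lc"), ids),
                      subclass_edges = data.frame(child = c("a", "b"),
                                                  parent = c("b", "c")))
  kg <- build_kg(list(ont), include_labels = TRUE)
  corpus <- build_opa2vec_corpus(kg)
  key <- vapply(corpus, paste, "", collapse = " ")
  sub_sents <- grep("subClassOf", key, value = TRUE)
  expect_length(sub_sents, 3)  # a<b, b<c asserted + a<c inferred
  expect_true("a subClassOf c" %in% sub_sents)
  expect_true("a label heart disease" %in% key)
  expect_equal(corpus[[which(key == "a label heart disease")]],
               c("a", "label", "heart", "disease"))

  single <- build_kg(list(toy_ontology(
    "S1", c("x", "y"), stats::setNames(c("lx", "ly"), c("x", "y")),
    subclass_edges = data.frame(child = "x", parent = "y"))))
  expect_equal(build_opa2vec_corpus(single), list(c("x", "subClassOf", "y")))
})

test_that("stay aggregation is an additive, permutation-invariant sum", {
  vec <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                dimnames = list(c("c1", "c2", "c3"), NULL))
  space <- structure(list(method = "rdf2vec", dimension = 2, vectors = vec,
                          meta = list()), class = "embedding_space")
  ann <- function(cls, stay = 1) data.frame(stay_id = rep(stay, length(cls)),
                                            feature_type = character(length(cls)),
                                            ontology = character(length(cls)),
                                            class_id = cls,
                                            stringsAsFactors = FALSE)
  expect_equal(embed_stay(ann("c1"), space), c(1, 2))
  expect_equal(embed_stay(ann(c("c1", "c2")), space), c(4, 6))
  expect_equal(embed_stay(ann(character(0)), space), c(0, 0))
  expect_error(embed_stay(ann("c9"), space), "missing from the embedding")

  # permutation invariance and additivity over disjoint sets
  ab <- ann(c("c1", "c3")); ba <- ann(c("c3", "c1"))
  expect_equal(embed_stay(ab, space), embed_stay(ba, space))
  expect_equal(embed_stay(ann(c("c1", "c2", "c3")), space),
               embed_stay(ann("c2"), space) +
                 embed_stay(ann(c("c1", "c3")), space))

  M <- embed_stays(rbind(ann("c1", 1), ann(c("c2", "c3"), 2)), space,
                   stay_ids = c(1, 2, 3))
  expect_equal(unname(M[1, ]), c(1, 2))
  expect_equal(unname(M[2, ]), c(8, 10))
  expect_equal(unname(M[3, ]), c(0, 0))
})

test_that("multi-ontology concatenation appends blocks in fixed order", {
  v <- list(A = c(1, 2), B = c(3, 4, 5))
  expect_equal(concat_multi_ontology(v, c("A", "B")), c(1, 2, 3, 4, 5))
  expect_equal(concat_multi_ontology(v["A"], "A"), c(1, 2))
  expect_equal(concat_multi_ontology(v["A"], c("A", "B"), dims = c(B = 3)),
               c(1, 2, 0, 0, 0))
  expect_error(concat_multi_ontology(v["A"], c("A", "B")), "no vector")
})

test_that("word2vec text export reproduces vectors exactly on import", {
  sp <- train_rdf2vec(chain_kg(), dimension = 7, epochs = 2, seed = 11)
  f <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(sp, f)
  back <- read_word2vec(f)
  expect_equal(back$dimension, 7)
  expect_equal(back$vectors[rownames(sp$vectors), ], sp$vectors,
               ignore_attr = TRUE, tolerance = 0)
})
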