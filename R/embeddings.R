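# Knowledge-graph embeddings: three families share one interface.
# (1) Random-walk + skip-gram: graph walks from every vertex are treated as
#     sentences for a skip-gram model (the RDF2Vec construction).
# (2) Translational: TransE, where a relation is a translation vector and a
#     triple (h, r, t) is plausible when h + r is close to t.
# (3) Axiom-corpus: asserted and inferred subclass axioms, annotation edges
#     and label words are verbalized into sentences and fed to the same
#     skip-gram trainer (an OPA2Vec-style construction trained on the
#     ontology's own corpus).

new_embedding_space <- function(method, vectors, meta) {
  structure(list(method = method, dimension = ncol(vectors),
                 vectors = vectors, meta = meta),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("embedding_space [%s]: %d tokens x %d dimensions\n",
              x$method, nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Retrieve the vector for a token
#' @param space An `embedding_space`.
#' @param token Vertex or relation token.
#' @return Numeric vector of length `space$dimension`.
#' @export
embedding_vector <- function(space, token) {
  assert_that(token %in% rownames(space$vectors),
              paste("token not in embedding space:", token))
  space$vectors[token, ]
}

# shared skip-gram entry point: sentences are character-token vectors
train_skipgram <- function(sentences, dimension, window, epochs, negative,
                           learning_rate, seed, extra_tokens = character(0)) {
  tokens <- unlist(sentences, use.names = FALSE)
  vocab <- sort(unique(c(tokens, extra_tokens)))
  counts <- table(factor(tokens, levels = vocab))
  counts <- pmax(as.integer(counts), 1L)  # never zero-weight a vertex
  enc <- lapply(sentences, function(s)
    match(s, vocab) - 1L)
  mat <- .sgns_train(enc, length(vocab), counts, as.integer(dimension),
                     as.integer(window), as.integer(epochs),
                     as.integer(negative), learning_rate, as.numeric(seed))
  rownames(mat) <- vocab
  mat
}

#' Train random-walk skip-gram embeddings over a knowledge graph
#'
#' Walks of at most `max_depth` edges are enumerated from every vertex
#' (capped at `max_walks` per root by uniform sampling) and fed as sentences
#' to skip-gram with negative sampling. Every vertex of the graph receives a
#' vector; training is deterministic under `seed`.
#'
#' @param kg A [build_kg()] result (non-empty).
#' @param dimension Embedding width (default 300).
#' @param max_walks,max_depth Walk budget per root and maximum edges per walk.
#' @param window,epochs,negative,learning_rate Skip-gram hyperparameters
#'   (window 5, 5 epochs, 5 negative samples, initial rate 0.025).
#' @param seed Integer seed.
#' @param mode Walk mode, `"prefix"` (default) or `"full"`; see
#'   [generate_walks()].
#' @param roots Optional subset of walk roots (default: all vertices).
#' @param include_relations Keep relation tokens in the walk sentences
#'   (default `TRUE`).
#' @return An `embedding_space` with `method = "rdf2vec"`.
#' @export
train_rdf2vec <- function(kg, dimension = 300, max_walks = 500, max_depth = 4,
                          window = 5, epochs = 5, negative = 5,
                          learning_rate = 0.025, seed = 1, mode = "prefix",
                          roots = NULL, include_relations = TRUE) {
  assert_that(is_scalar_number(dimension) && dimension >= 1,
              "dimension must be >= 1")
  vertices <- c(kg$class_vertices, kg$instance_vertices)
  assert_that(length(vertices) > 0, "KG is empty")
  corpus <- walk_corpus(kg, max_depth, max_walks, seed, mode, roots,
                        include_relations)
  mat <- train_skipgram(corpus, dimension, window, epochs, negative,
                        learning_rate, seed, extra_tokens = vertices)
  new_embedding_space("rdf2vec", mat,
                      list(seed = seed, epochs = epochs, window = window,
                           negative = negative, max_walks = max_walks,
                           max_depth = max_depth, mode = mode,
                           learning_rate = learning_rate))
}

#' Verbalize a knowledge graph into an axiom corpus
#'
#' One sentence per asserted class edge, per inferred subclass edge
#' (transitive closure of the subclass relation), per annotation edge, and
#' per label triple with the label word-split.
#'
#' @param kg A [build_kg()] result.
#' @return List of character token vectors.
#' @export
build_opa2vec_corpus <- function(kg) {
  sentences <- list()
  ed <- kg$class_edges
  for (i in seq_len(nrow(ed))) {
    sentences[[length(sentences) + 1]] <-
      c(ed$subject[i], ed$predicate[i], ed$object[i])
  }
  sub <- data.frame(child = ed$subject[ed$predicate == "subClassOf"],
                    parent = ed$object[ed$predicate == "subClassOf"],
                    stringsAsFactors = FALSE)
  inferred <- subclass_closure(sub)
  for (i in seq_len(nrow(inferred))) {
    sentences[[length(sentences) + 1]] <-
      c(inferred$child[i], "subClassOf", inferred$parent[i])
  }
  ea <- kg$annotation_edges
  for (i in seq_len(nrow(ea))) {
    sentences[[length(sentences) + 1]] <-
      c(ea$subject[i], ea$predicate[i], ea$object[i])
  }
  lt <- kg$label_triples
  for (i in seq_len(nrow(lt))) {
    sentences[[length(sentences) + 1]] <-
      c(lt$subject[i], lt$predicate[i],
        strsplit(normalize_text(lt$object[i]), " ", fixed = TRUE)[[1]])
  }
  sentences
}

#' Train axiom-corpus embeddings
#'
#' Skip-gram over the [build_opa2vec_corpus()] sentences. Unlike the original
#' formulation, the language model is trained on the generated corpus itself
#' rather than initialized from a literature-pretrained model.
#'
#' @inheritParams train_rdf2vec
#' @return An `embedding_space` with `method = "opa2vec"`.
#' @export
train_opa2vec <- function(kg, dimension = 300, window = 5, epochs = 5,
                          negative = 5, learning_rate = 0.025, seed = 1) {
  assert_that(is_scalar_number(dimension) && dimension >= 1,
              "dimension must be >= 1")
  vertices <- c(kg$class_vertices, kg$instance_vertices)
  assert_that(length(vertices) > 0, "KG is empty")
  corpus <- build_opa2vec_corpus(kg)
  mat <- train_skipgram(corpus, dimension, window, epochs, negative,
                        learning_rate, seed, extra_tokens = vertices)
  new_embedding_space("opa2vec", mat,
                      list(seed = seed, epochs = epochs, window = window,
                           negative = negative,
                           learning_rate = learning_rate))
}

#' Translational triple score
#'
#' `||h + r - t||` under the L1 or L2 norm; zero means the relation
#' translates the head exactly onto the tail.
#'
#' @param h_vec,r_vec,t_vec Equal-length numeric vectors.
#' @param norm `"L2"` (default) or `"L1"`.
#' @return Non-negative scalar.
#' @export
transe_score <- function(h_vec, r_vec, t_vec, norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  assert_that(length(h_vec) == length(r_vec) &&
                length(r_vec) == length(t_vec),
              "dimension mismatch between h, r and t")
  x <- h_vec + r_vec - t_vec
  if (norm == "L2") sqrt(sum(x^2)) else sum(abs(x))
}

#' Train TransE embeddings
#'
#' Margin-ranking loss over (true, corrupted) triple pairs with uniform
#' head-or-tail corruption; corrupted triples present in the graph are
#' rejected (filtered sampling). Entity vectors are renormalized to unit L2
#' at the end of every epoch. Trains on class and annotation edges (label
#' triples are literals, not entities).
#'
#' @param kg A [build_kg()] result with at least one triple.
#' @param dimension Embedding width (default 300).
#' @param margin Ranking margin (> 0).
#' @param learning_rate Gradient step size.
#' @param epochs Full passes over the triples.
#' @param negatives_per_positive Corrupted triples per true triple.
#' @param seed Integer seed.
#' @param norm Scoring norm, `"L2"` (default) or `"L1"`.
#' @return An `embedding_space` with `method = "transe"`; relation vectors
#'   are stored alongside entity vectors.
#' @export
train_transe <- function(kg, dimension = 300, margin = 1,
                         learning_rate = 0.01, epochs = 100,
                         negatives_per_positive = 1, seed = 1,
                         norm = c("L2", "L1")) {
  norm <- match.arg(norm)
  assert_that(margin > 0, "margin must be > 0")
  assert_that(is_scalar_number(dimension) && dimension >= 1,
              "dimension must be >= 1")
  triples <- rbind(kg$class_edges, kg$annotation_edges)
  assert_that(nrow(triples) >= 1, "KG must contain at least one triple")
  entities <- sort(unique(c(kg$class_vertices, kg$instance_vertices,
                            triples$subject, triples$object)))
  relations <- sort(unique(triples$predicate))
  ne <- length(entities); nr <- length(relations); d <- as.integer(dimension)
  hi <- match(triples$subject, entities)
  ri <- match(triples$predicate, relations)
  ti <- match(triples$object, entities)
  seen <- paste(hi, ri, ti)

  with_local_seed(seed, {
    bound <- 6 / sqrt(d)
    E <- matrix(stats::runif(ne * d, -bound, bound), ne, d)
    R <- matrix(stats::runif(nr * d, -bound, bound), nr, d)
    R <- R / pmax(sqrt(rowSums(R^2)), 1e-12)
    m <- nrow(triples)
    for (ep in seq_len(epochs)) {
      for (neg in seq_len(negatives_per_positive)) {
        corrupt_head <- stats::runif(m) < 0.5
        ch <- hi; ct <- ti
        repl <- sample.int(ne, m, replace = TRUE)
        ch[corrupt_head] <- repl[corrupt_head]
        ct[!corrupt_head] <- repl[!corrupt_head]
        # filtered sampling: resample corrupted triples that exist in the KG
        for (tries in 1:10) {
          bad <- paste(ch, ri, ct) %in% seen
          if (!any(bad)) break
          repl2 <- sample.int(ne, sum(bad), replace = TRUE)
          chb <- corrupt_head[bad]
          ch[bad][chb] <- repl2[chb]
          ct[bad][!chb] <- repl2[!chb]
        }
        P <- E[hi, , drop = FALSE] + R[ri, , drop = FALSE] -
          E[ti, , drop = FALSE]
        N <- E[ch, , drop = FALSE] + R[ri, , drop = FALSE] -
          E[ct, , drop = FALSE]
        if (norm == "L2") {
          dp <- sqrt(rowSums(P^2)); dn <- sqrt(rowSums(N^2))
          GP <- P / pmax(dp, 1e-12); GN <- N / pmax(dn, 1e-12)
        } else {
          dp <- rowSums(abs(P)); dn <- rowSums(abs(N))
          GP <- sign(P); GN <- sign(N)
        }
        viol <- margin + dp - dn > 0
        if (!any(viol)) next
        GP <- GP[viol, , drop = FALSE]; GN <- GN[viol, , drop = FALSE]
        idx_e <- c(hi[viol], ti[viol], ch[viol], ct[viol])
        grad_e <- rbind(GP, -GP, -GN, GN)
        upd <- rowsum(grad_e, idx_e)
        rows <- as.integer(rownames(upd))
        E[rows, ] <- E[rows, ] - learning_rate * upd
        upd_r <- rowsum(GP - GN, ri[viol])
        rrows <- as.integer(rownames(upd_r))
        R[rrows, ] <- R[rrows, ] - learning_rate * upd_r
      }
      E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
    }
    vec <- rbind(E, R)
    rownames(vec) <- c(entities, relations)
    new_embedding_space("transe", vec,
                        list(seed = seed, epochs = epochs, margin = margin,
                             learning_rate = learning_rate, norm = norm,
                             negatives_per_positive = negatives_per_positive,
                             entities = entities, relations = relations))
  })
}

#' Aggregate a stay's annotations into one vector
#'
#' The per-ontology stay vector is the sum of the embedding vectors of the
#' classes annotating the stay (empty sum: the zero vector). Aggregation is
#' permutation-invariant and additive over disjoint annotation sets.
#'
#' @param annotations Annotation data frame rows for one stay.
#' @param space An `embedding_space` trained over the corresponding KG.
#' @param ontology Optional ontology name to restrict the annotations.
#' @return Numeric vector of length `space$dimension`.
#' @export
embed_stay <- function(annotations, space, ontology = NULL) {
  if (!is.null(ontology)) {
    annotations <- annotations[annotations$ontology == ontology, ,
                               drop = FALSE]
  }
  cls <- annotations$class_id
  if (length(cls) == 0) return(numeric(space$dimension))
  missing <- setdiff(unique(cls), rownames(space$vectors))
  if (length(missing) > 0) {
    stop("annotation classes missing from the embedding space: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  colSums(space$vectors[cls, , drop = FALSE])
}

#' Aggregate stay vectors for a whole cohort
#'
#' @param annotations Full annotation data frame.
#' @param space An `embedding_space`.
#' @param stay_ids Stay identifiers defining row order of the result.
#' @param ontology Optional ontology restriction.
#' @return Matrix `length(stay_ids) x space$dimension`, zero rows for stays
#'   without annotations.
#' @export
embed_stays <- function(annotations, space, stay_ids, ontology = NULL) {
  if (!is.null(ontology)) {
    annotations <- annotations[annotations$ontology == ontology, ,
                               drop = FALSE]
  }
  annotations <- annotations[annotations$stay_id %in% stay_ids, , drop = FALSE]
  out <- matrix(0, length(stay_ids), space$dimension,
                dimnames = list(as.character(stay_ids), NULL))
  if (nrow(annotations) == 0) return(out)
  missing <- setdiff(unique(annotations$class_id), rownames(space$vectors))
  if (length(missing) > 0) {
    stop("annotation classes missing from the embedding space: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  agg <- rowsum(space$vectors[annotations$class_id, , drop = FALSE],
                group = annotations$stay_id)
  out[rownames(agg), ] <- agg
  out
}

#' Concatenate per-ontology stay vectors
#'
#' Vectors (or row-matched matrices) are appended in `ontology_order`;
#' ontologies missing from `vectors` contribute zero blocks of the width
#' given in `dims`.
#'
#' @param vectors Named list of numeric vectors or matrices.
#' @param ontology_order Character vector fixing the block order.
#' @param dims Optional named widths for ontologies absent from `vectors`.
#' @return One concatenated vector (or matrix).
#' @export
concat_multi_ontology <- function(vectors, ontology_order, dims = NULL) {
  blocks <- lapply(ontology_order, function(o) {
    v <- vectors[[o]]
    if (!is.null(v)) return(v)
    w <- dims[[o]]
    if (is.null(w)) stop("no vector and no dimension for ontology ", o,
                         call. = FALSE)
    proto <- Filter(Negate(is.null), vectors)[[1]]
    if (is.matrix(proto)) matrix(0, nrow(proto), w) else numeric(w)
  })
  if (is.matrix(blocks[[1]])) do.call(cbind, blocks) else unlist(blocks,
                                                                 use.names = FALSE)
}

#' Export / import embeddings in word2vec text format
#'
#' Header line `<count> <dimension>`, then one token and its vector per line,
#' space-separated, full precision (the round trip reproduces the numbers
#' exactly).
#'
#' @param space An `embedding_space`.
#' @param path File path.
#' @param method Method tag attached on import.
#' @return `path` invisibly (writer); an `embedding_space` (reader).
#' @export
write_word2vec <- function(space, path) {
  m <- space$vectors
  lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(gsub(" ", "_", rownames(m)[i]),
                       formatC(m[i, ], format = "g", digits = 17)),
                     collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path, method = "imported") {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(mat) <- vapply(parts, `[`, "", 1)
  new_embedding_space(method, mat, list(source = path))
}
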