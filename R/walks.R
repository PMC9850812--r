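# Graph walks for random-walk embeddings. Walks follow edge direction
# (child -> parent for subclass edges, instance -> class for annotation
# edges), so they climb toward ancestors, and alternate vertex and relation
# tokens.

kg_adjacency <- function(kg, bidirectional = FALSE) {
  ed <- rbind(kg$class_edges, kg$annotation_edges)
  if (bidirectional && nrow(ed) > 0) {
    ed <- rbind(ed, data.frame(subject = ed$object,
                               predicate = paste0("inv_", ed$predicate),
                               object = ed$subject, stringsAsFactors = FALSE))
  }
  if (nrow(ed) == 0) return(list())
  ed <- ed[order(ed$subject, ed$predicate, ed$object), , drop = FALSE]
  split(ed[c("predicate", "object")], ed$subject)
}

enumerate_walks <- function(adj, root, max_depth, prefix_inclusive = TRUE) {
  walks <- list()
  recurse <- function(path, vertex, depth) {
    if (prefix_inclusive || depth == max_depth ||
        is.null(adj[[vertex]]) || nrow(adj[[vertex]]) == 0) {
      walks[[length(walks) + 1]] <<- path
    }
    if (depth == max_depth) return()
    nb <- adj[[vertex]]
    if (is.null(nb) || nrow(nb) == 0) return()
    for (j in seq_len(nrow(nb))) {
      recurse(c(path, nb$predicate[j], nb$object[j]), nb$object[j], depth + 1L)
    }
  }
  recurse(root, root, 0L)
  walks
}

#' Generate graph walks from a root vertex
#'
#' Enumerates every directed walk of at most `max_depth` edges rooted at
#' `root` (prefix-inclusive by default: each proper prefix, including the
#' lone root, is itself a walk; in `"full"` mode only maximal walks are
#' kept). If the enumeration exceeds `max_walks`, a uniform sample of
#' `max_walks` walks is drawn under `seed`. Tokens alternate vertex and
#' relation identifiers.
#'
#' @param kg A [build_kg()] result.
#' @param root Vertex identifier in the graph.
#' @param max_depth Maximum number of edges per walk (default 4).
#' @param max_walks Cap on walks per root (default 500).
#' @param seed Seed for the sampling step.
#' @param mode `"prefix"` (default) or `"full"`.
#' @param bidirectional Also walk against edge direction (default `FALSE`).
#' @param include_relations Keep relation tokens between vertex tokens
#'   (default `TRUE`); `FALSE` yields vertex-only walks.
#' @return A `walk_set`: `root`, `walks` (list of token vectors), `max_depth`,
#'   `mode` (`"exhaustive"` or `"sampled"`).
#' @export
generate_walks <- function(kg, root, max_depth = 4, max_walks = 500,
                           seed = 1, mode = c("prefix", "full"),
                           bidirectional = FALSE, include_relations = TRUE) {
  mode <- match.arg(mode)
  vertices <- c(kg$class_vertices, kg$instance_vertices)
  assert_that(root %in% vertices, paste("root not in the KG:", root))
  adj <- kg_adjacency(kg, bidirectional)
  walks_from_adjacency(adj, root, max_depth, max_walks, seed, mode,
                       include_relations)
}

walks_from_adjacency <- function(adj, root, max_depth, max_walks, seed, mode,
                                 include_relations = TRUE) {
  walks <- enumerate_walks(adj, root, max_depth,
                           prefix_inclusive = (mode == "prefix"))
  generation <- "exhaustive"
  if (length(walks) > max_walks) {
    keep <- with_local_seed(seed, sample(length(walks), max_walks))
    walks <- walks[sort(keep)]
    generation <- "sampled"
  }
  if (!include_relations) {
    walks <- lapply(walks, function(w) w[seq(1, length(w), by = 2)])
  }
  structure(list(root = root, walks = walks, max_depth = max_depth,
                 mode = generation),
            class = "walk_set")
}

#' @export
print.walk_set <- function(x, ...) {
  cat(sprintf("walk_set from '%s': %d walks (depth <= %d, %s)\n",
              x$root, length(x$walks), x$max_depth, x$mode))
  invisible(x)
}

# walks from every vertex, as one corpus (list of token vectors)
walk_corpus <- function(kg, max_depth = 4, max_walks = 500, seed = 1,
                        mode = "prefix", roots = NULL,
                        include_relations = TRUE) {
  adj <- kg_adjacency(kg)
  roots <- roots %||% c(kg$class_vertices, kg$instance_vertices)
  out <- vector("list", length(roots))
  for (i in seq_along(roots)) {
    ws <- walks_from_adjacency(adj, roots[i], max_depth, max_walks,
                               derive_seed(seed, i), mode, include_relations)
    out[[i]] <- ws$walks
  }
  unlist(out, recursive = FALSE, use.names = FALSE)
}
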