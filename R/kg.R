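# Patient knowledge graph: class vertices (ontology classes), instance
# vertices (one per ICU stay), typed class-class edges from the ontologies,
# and annotation edges linking each stay to the classes that describe it.

.ANNOT_PRED <- "annotatedBy"
.STAY_PREFIX <- "stay:"

stay_vertex <- function(stay_id) paste0(.STAY_PREFIX, stay_id)

#' Build the patient knowledge graph
#'
#' Class vertices are the union of the ontologies' classes; instance vertices
#' are the stays present in the annotation table; class edges are the
#' ontology subclass edges (typed triples); annotation edges link each stay
#' to each class annotating it through a single fixed predicate, one edge per
#' distinct (stay, class) pair.
#'
#' @param ontologies List of [toy_ontology()] objects.
#' @param annotations Annotation data frame (`stay_id`, `feature_type`,
#'   `ontology`, `class_id`) or `NULL`/empty for a bare ontology graph.
#' @param include_labels Attach one label triple per class (default `FALSE`).
#' @return A `knowledge_graph`: `class_vertices`, `instance_vertices`,
#'   `class_edges` (subject, predicate, object), `annotation_edges`,
#'   `label_triples`.
#' @export
build_kg <- function(ontologies, annotations = NULL, include_labels = FALSE) {
  if (inherits(ontologies, "toy_ontology")) ontologies <- list(ontologies)
  class_vertices <- sort(unique(unlist(lapply(ontologies, `[[`, "classes"),
                                       use.names = FALSE)))
  class_edges <- do.call(rbind, lapply(ontologies, function(o) {
    if (nrow(o$subclass_edges) == 0) return(NULL)
    data.frame(subject = o$subclass_edges$child, predicate = "subClassOf",
               object = o$subclass_edges$parent, stringsAsFactors = FALSE)
  }))
  if (is.null(class_edges)) {
    class_edges <- data.frame(subject = character(), predicate = character(),
                              object = character(), stringsAsFactors = FALSE)
  }
  rownames(class_edges) <- NULL
  if (is.null(annotations) || nrow(annotations) == 0) {
    instance_vertices <- character(0)
    annotation_edges <- data.frame(subject = character(),
                                   predicate = character(),
                                   object = character(),
                                   stringsAsFactors = FALSE)
  } else {
    unknown <- setdiff(unique(annotations$class_id), class_vertices)
    if (length(unknown) > 0) {
      stop("annotations reference classes absent from the ontologies: ",
           paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
    }
    pairs <- unique(data.frame(stay = annotations$stay_id,
                               class = annotations$class_id,
                               stringsAsFactors = FALSE))
    pairs <- pairs[order(pairs$stay, pairs$class), , drop = FALSE]
    instance_vertices <- stay_vertex(sort(unique(annotations$stay_id)))
    annotation_edges <- data.frame(subject = stay_vertex(pairs$stay),
                                   predicate = .ANNOT_PRED,
                                   object = pairs$class,
                                   stringsAsFactors = FALSE)
    rownames(annotation_edges) <- NULL
  }
  label_triples <- data.frame(subject = character(), predicate = character(),
                              object = character(), stringsAsFactors = FALSE)
  if (include_labels) {
    label_triples <- do.call(rbind, lapply(ontologies, function(o) {
      data.frame(subject = o$classes, predicate = "label",
                 object = unname(o$labels[o$classes]),
                 stringsAsFactors = FALSE)
    }))
    rownames(label_triples) <- NULL
  }
  structure(list(class_vertices = class_vertices,
                 instance_vertices = instance_vertices,
                 class_edges = class_edges,
                 annotation_edges = annotation_edges,
                 label_triples = label_triples),
            class = "knowledge_graph")
}

kg_triples <- function(kg, include_labels = TRUE) {
  out <- rbind(kg$class_edges, kg$annotation_edges)
  if (include_labels) out <- rbind(out, kg$label_triples)
  out
}

#' Knowledge-graph statistics
#'
#' Distinct subjects, distinct objects, distinct predicates and total triple
#' count over class edges, annotation edges and (optionally) label triples.
#'
#' @param kg A [build_kg()] result.
#' @param include_labels Count label triples too (default `TRUE`).
#' @return Named list `triples`, `subjects`, `objects`, `predicates`.
#' @export
kg_stats <- function(kg, include_labels = TRUE) {
  tr <- kg_triples(kg, include_labels)
  list(triples = nrow(tr),
       subjects = length(unique(tr$subject)),
       objects = length(unique(tr$object)),
       predicates = length(unique(tr$predicate)))
}

#' @export
print.knowledge_graph <- function(x, ...) {
  s <- kg_stats(x)
  cat(sprintf(paste0("knowledge_graph: %d class vertices, %d instance ",
                     "vertices, %d triples (%d predicates)\n"),
              length(x$class_vertices), length(x$instance_vertices),
              s$triples, s$predicates))
  invisible(x)
}

kg_uri <- function(id) {
  ifelse(startsWith(id, .STAY_PREFIX),
         paste0("urn:kg:", id), paste0("urn:kg:class:", id))
}

kg_unuri <- function(uri) {
  ifelse(startsWith(uri, "urn:kg:class:"),
         sub("^urn:kg:class:", "", uri), sub("^urn:kg:", "", uri))
}

#' Export / import a knowledge graph as N-Triples
#'
#' The round trip preserves the triple multiset exactly. Unknown predicates
#' on import are kept as typed class edges (permissive schema); literal
#' objects become label triples.
#'
#' @param kg A `knowledge_graph`.
#' @param path File path.
#' @return `path` invisibly (export); a `knowledge_graph` (import).
#' @export
export_ntriples <- function(kg, path) {
  pred_uri <- function(p) paste0("urn:kg:pred:", p)
  lines <- c(
    sprintf("<%s> <%s> <%s> .", kg_uri(kg$class_edges$subject),
            pred_uri(kg$class_edges$predicate), kg_uri(kg$class_edges$object)),
    sprintf("<%s> <%s> <%s> .", kg_uri(kg$annotation_edges$subject),
            pred_uri(kg$annotation_edges$predicate),
            kg_uri(kg$annotation_edges$object)),
    if (nrow(kg$label_triples) > 0) {
      sprintf('<%s> <%s> "%s" .', kg_uri(kg$label_triples$subject),
              pred_uri(kg$label_triples$predicate),
              nt_escape(kg$label_triples$object))
    })
  # isolated vertices survive the round trip through a type-marker triple
  linked <- unique(c(kg$class_edges$subject, kg$class_edges$object,
                     kg$annotation_edges$object, kg$label_triples$subject))
  iso <- setdiff(kg$class_vertices, linked)
  if (length(iso) > 0) {
    lines <- c(lines, sprintf("<%s> <urn:kg:pred:a> <urn:kg:Class> .",
                              kg_uri(iso)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_ntriples
#' @export
import_ntriples <- function(path) {
  tr <- parse_nt_lines(readLines(path), path)
  pred <- sub("^urn:kg:pred:", "", tr$predicate)
  subj <- kg_unuri(tr$subject)
  is_lit <- !nzchar(tr$object_uri)
  is_marker <- !is_lit & tr$object_uri == "urn:kg:Class"
  obj <- kg_unuri(tr$object_uri)
  is_annot <- !is_lit & !is_marker & startsWith(subj, .STAY_PREFIX)
  is_class_edge <- !is_lit & !is_marker & !is_annot
  kg <- structure(list(
    class_vertices = sort(unique(c(subj[is_class_edge], obj[is_class_edge],
                                   obj[is_annot], subj[is_lit],
                                   subj[is_marker]))),
    instance_vertices = sort(unique(subj[is_annot])),
    class_edges = data.frame(subject = subj[is_class_edge],
                             predicate = pred[is_class_edge],
                             object = obj[is_class_edge],
                             stringsAsFactors = FALSE),
    annotation_edges = data.frame(subject = subj[is_annot],
                                  predicate = pred[is_annot],
                                  object = obj[is_annot],
                                  stringsAsFactors = FALSE),
    label_triples = data.frame(subject = subj[is_lit],
                               predicate = pred[is_lit],
                               object = tr$object_lit[is_lit],
                               stringsAsFactors = FALSE)),
    class = "knowledge_graph")
  kg
}
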