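# Toy biomedical ontologies: rooted subclass hierarchies with labels and
# synonyms, standing in for the large curated vocabularies (a general clinical
# thesaurus, a lab-test vocabulary, a diagnosis/procedure classification and a
# drug ontology) that annotate real EHR data.

.RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"
.RDFS_LABEL    <- "http://www.w3.org/2000/01/rdf-schema#label"
.SYNONYM_PRED  <- "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym"

#' Construct a toy ontology object
#'
#' A `toy_ontology` is a rooted, acyclic subclass hierarchy with one primary
#' label per class and optional synonyms. It is the minimal structure the
#' annotation and embedding stages require: classes, `is-a` edges, and a
#' lexical layer.
#'
#' @param acronym Short identifier for the ontology (e.g. `"NCIT"`).
#' @param classes Character vector of class identifiers.
#' @param labels Named character vector: class identifier to primary label.
#' @param synonyms Named list: class identifier to character vector of
#'   alternative labels. Classes may be absent (no synonyms).
#' @param subclass_edges Data frame with columns `child`, `parent`.
#' @return An object of class `toy_ontology` with fields `acronym`, `classes`,
#'   `labels`, `synonyms`, `subclass_edges` and `roots` (classes without a
#'   parent).
#' @export
toy_ontology <- function(acronym, classes, labels, synonyms = list(),
                         subclass_edges = data.frame(child = character(),
                                                     parent = character())) {
  ont <- structure(
    list(acronym = as.character(acronym),
         classes = as.character(classes),
         labels = labels,
         synonyms = synonyms,
         subclass_edges = data.frame(child = as.character(subclass_edges$child),
                                     parent = as.character(subclass_edges$parent),
                                     stringsAsFactors = FALSE),
         roots = setdiff(classes, subclass_edges$child)),
    class = "toy_ontology")
  validate_toy_ontology(ont)
  ont
}

#' Validate a toy ontology
#'
#' Checks the structural invariants: edge endpoints are known classes, every
#' class has exactly one non-empty primary label, and the subclass relation is
#' acyclic (a topological order exists).
#'
#' @param ont A `toy_ontology`.
#' @return `ont`, invisibly; errors on violation.
#' @export
validate_toy_ontology <- function(ont) {
  assert_that(inherits(ont, "toy_ontology"), "not a toy_ontology")
  cls <- ont$classes
  assert_that(!anyDuplicated(cls), "duplicate class identifiers")
  ed <- ont$subclass_edges
  assert_that(all(ed$child %in% cls) && all(ed$parent %in% cls),
              "subclass edge endpoint not among classes")
  assert_that(all(cls %in% names(ont$labels)),
              "every class needs a primary label")
  assert_that(all(nzchar(ont$labels[cls])), "labels must be non-empty")
  # Kahn's algorithm on child -> parent edges
  if (nrow(ed) > 0) {
    indeg <- table(factor(ed$child, levels = cls))
    queue <- cls[indeg == 0]
    seen <- 0L
    parents_of <- split(ed$parent, ed$child)
    children_of <- split(ed$child, ed$parent)
    indeg <- as.integer(indeg)
    names(indeg) <- cls
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
      for (ch in children_of[[v]] %||% character()) {
        indeg[[ch]] <- indeg[[ch]] - 1L
        if (indeg[[ch]] == 0L) queue <- c(queue, ch)
      }
    }
    assert_that(seen == length(cls), "subclass relation contains a cycle")
  }
  invisible(ont)
}

#' @export
print.toy_ontology <- function(x, ...) {
  cat(sprintf("toy_ontology '%s': %d classes, %d subclass edges, %d roots\n",
              x$acronym, length(x$classes), nrow(x$subclass_edges),
              length(x$roots)))
  invisible(x)
}

# deterministic synthetic vocabulary ----------------------------------------

.SYLLABLES <- c("car", "di", "ne", "phro", "hepa", "to", "os", "teo", "myo",
                "derma", "vascu", "pulmo", "gastro", "entero", "cardi", "reno",
                "cepha", "algia", "itis", "osis", "emia", "pathy", "gram",
                "scopy", "ectomy", "plasty", "trophy", "lysis", "stasis",
                "pnea", "rrhea", "cyte", "blasto", "oma", "genic", "static")

.QUALIFIERS <- c("acute", "chronic", "severe", "mild", "primary", "secondary",
                 "recurrent", "benign", "malignant", "idiopathic", "diffuse",
                 "focal")

# n unique pronounceable pseudo-medical words, drawn from the active RNG
make_words <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:3, 1)
    w <- paste0(sample(.SYLLABLES, k, replace = TRUE), collapse = "")
    if (!w %in% out) out <- c(out, w)
  }
  out
}

make_class_ids <- function(acronym, n, id_style) {
  switch(id_style,
    curie = sprintf("%s:C%04d", acronym, seq_len(n)),
    icd9 = {
      n_dx <- ceiling(n / 2)
      dx <- sprintf("%03d.%d", 100 + (seq_len(n_dx) - 1) %/% 10,
                    (seq_len(n_dx) - 1) %% 10)
      n_px <- n - n_dx
      px <- if (n_px > 0) {
        sprintf("%02d.%02d", 10 + (seq_len(n_px) - 1) %/% 100,
                (seq_len(n_px) - 1) %% 100)
      } else character()
      c(dx, px)
    },
    loinc = sprintf("%d-%d", 1000 + seq_len(n), seq_len(n) %% 10),
    stop("unknown id_style: ", id_style))
}

#' Generate a toy ontology
#'
#' Builds a complete `branching_factor`-ary subclass tree over `n_classes`
#' classes with deterministic synthetic labels and synonyms. The tree shape is
#' a function of `n_classes` and `branching_factor` only; the lexical layer is
#' a function of `seed`, so the same arguments always yield a byte-identical
#' ontology.
#'
#' @param acronym Ontology acronym; also prefixes `curie`-style identifiers.
#' @param n_classes Number of classes (>= 1).
#' @param branching_factor Children per internal node (>= 1).
#' @param synonyms_per_class Synonyms attached to every class (>= 0).
#' @param seed Integer RNG seed for the lexical layer.
#' @param id_style One of `"curie"` (default, `ACR:C0001`-style), `"icd9"`
#'   (first half diagnosis-style `dddd.d`, second half procedure-style
#'   `dd.dd`), or `"loinc"` (`dddd-d`-style codes).
#' @return A [toy_ontology()].
#' @examples
#' ont <- generate_toy_ontology("NCIT", n_classes = 7, branching_factor = 2,
#'                              synonyms_per_class = 1, seed = 1)
#' nrow(ont$subclass_edges)  # 6: a tree has n - 1 edges
#' @export
generate_toy_ontology <- function(acronym, n_classes, branching_factor = 2,
                                  synonyms_per_class = 2, seed = 1,
                                  id_style = c("curie", "icd9", "loinc")) {
  assert_that(is_scalar_number(n_classes) && n_classes >= 1,
              "n_classes must be a positive count")
  assert_that(is_scalar_number(branching_factor) && branching_factor >= 1,
              "branching_factor must be >= 1")
  id_style <- match.arg(id_style)
  n_classes <- as.integer(n_classes)

  ids <- make_class_ids(acronym, n_classes, id_style)
  with_local_seed(seed, {
    words <- make_words(2L * n_classes + 20L)
    labels <- character(n_classes)
    used <- character(0)
    for (i in seq_len(n_classes)) {
      repeat {
        lab <- paste(sample(.QUALIFIERS, 1), sample(words, 1), sample(words, 1))
        if (!lab %in% used) break
      }
      used <- c(used, lab)
      labels[i] <- lab
    }
    names(labels) <- ids
    synonyms <- list()
    if (synonyms_per_class > 0) {
      suffixes <- c("disorder", "syndrome", "finding", "process", "nos")
      for (i in seq_len(n_classes)) {
        parts <- strsplit(labels[i], " ")[[1]]
        syns <- character(0)
        while (length(syns) < synonyms_per_class) {
          s <- if (stats::runif(1) < 0.5) {
            paste(c(rev(parts[-1]), parts[1]), collapse = " ")
          } else {
            paste(labels[i], sample(suffixes, 1))
          }
          if (!s %in% syns && s != labels[i]) syns <- c(syns, s)
        }
        synonyms[[ids[i]]] <- syns
      }
    }
    edges <- if (n_classes > 1) {
      child <- ids[2:n_classes]
      parent <- ids[((2:n_classes) - 2L) %/% as.integer(branching_factor) + 1L]
      data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
    } else {
      data.frame(child = character(), parent = character(),
                 stringsAsFactors = FALSE)
    }
    toy_ontology(acronym, ids, labels, synonyms, edges)
  })
}

#' Standard four-ontology toy suite with an NDC mapping table
#'
#' Mirrors the multi-ontology annotation setting: a general clinical thesaurus
#' (`NCIT` stand-in), a lab vocabulary (`LOINC` stand-in), a combined
#' diagnosis/procedure classification (`ICD9` stand-in) and a drug ontology
#' (`DRON` stand-in) together with a national-drug-code lookup table mapping
#' NDC-like codes to drug-ontology classes.
#'
#' @param seed Integer seed.
#' @param sizes Named integer vector of class counts per ontology.
#' @param synonyms_per_class Synonyms per class in each ontology.
#' @return List with `ontologies` (named list of [toy_ontology()]) and
#'   `ndc_table` (data frame `ndc`, `class_id`).
#' @export
toy_ontology_suite <- function(seed = 1,
                               sizes = c(NCIT = 150, LOINC = 80,
                                         ICD9 = 120, DRON = 60),
                               synonyms_per_class = 2) {
  onts <- list(
    NCIT = generate_toy_ontology("NCIT", sizes[["NCIT"]], branching_factor = 3,
                                 synonyms_per_class, seed = derive_seed(seed, 1)),
    LOINC = generate_toy_ontology("LOINC", sizes[["LOINC"]], branching_factor = 4,
                                  synonyms_per_class, seed = derive_seed(seed, 2),
                                  id_style = "loinc"),
    ICD9 = generate_toy_ontology("ICD9", sizes[["ICD9"]], branching_factor = 3,
                                 synonyms_per_class, seed = derive_seed(seed, 3),
                                 id_style = "icd9"),
    DRON = generate_toy_ontology("DRON", sizes[["DRON"]], branching_factor = 3,
                                 synonyms_per_class, seed = derive_seed(seed, 4)))
  dron_ids <- onts$DRON$classes
  ndc <- with_local_seed(derive_seed(seed, 5), {
    sprintf("%05d-%04d-%02d",
            sample(10000:99999, length(dron_ids), replace = TRUE),
            seq_along(dron_ids), sample(0:99, length(dron_ids), replace = TRUE))
  })
  list(ontologies = onts,
       ndc_table = data.frame(ndc = ndc, class_id = dron_ids,
                              stringsAsFactors = FALSE))
}

# hierarchy helpers ----------------------------------------------------------

#' Descendants of a set of classes
#'
#' @param ont A [toy_ontology()].
#' @param class_ids Seed classes.
#' @param include_self Include the seed classes themselves (default `TRUE`).
#' @return Character vector of class identifiers.
#' @export
class_descendants <- function(ont, class_ids, include_self = TRUE) {
  children_of <- split(ont$subclass_edges$child, ont$subclass_edges$parent)
  out <- frontier <- intersect(class_ids, ont$classes)
  while (length(frontier) > 0) {
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  if (!include_self) out <- setdiff(out, class_ids)
  out
}

# transitive closure of (child, parent) subclass pairs, asserted pairs excluded
subclass_closure <- function(edges) {
  parents_of <- split(edges$parent, edges$child)
  res_child <- character(0); res_parent <- character(0)
  for (ch in unique(edges$child)) {
    anc <- character(0)
    frontier <- parents_of[[ch]]
    while (length(frontier) > 0) {
      anc <- union(anc, frontier)
      frontier <- setdiff(
        unique(unlist(parents_of[frontier], use.names = FALSE)), anc)
    }
    inferred <- setdiff(anc, parents_of[[ch]])
    res_child <- c(res_child, rep(ch, length(inferred)))
    res_parent <- c(res_parent, inferred)
  }
  data.frame(child = res_child, parent = res_parent, stringsAsFactors = FALSE)
}

# N-Triples / TSV serialization ----------------------------------------------

nt_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))
nt_unescape <- function(x) gsub("\\\\\\\\", "\\\\", gsub('\\\\"', '"', x))

onto_uri <- function(acronym, id) sprintf("urn:onto:%s:%s", acronym, id)

#' Write a toy ontology as N-Triples
#'
#' Emits subclass triples, one `rdfs:label` triple per class and one exact
#' synonym triple per synonym. Class URIs take the form
#' `urn:onto:<acronym>:<class id>`.
#'
#' @param ont A [toy_ontology()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ontology_ntriples <- function(ont, path) {
  lines <- character(0)
  ed <- ont$subclass_edges
  if (nrow(ed) > 0) {
    lines <- c(lines, sprintf("<%s> <%s> <%s> .",
                              onto_uri(ont$acronym, ed$child), .RDFS_SUBCLASS,
                              onto_uri(ont$acronym, ed$parent)))
  }
  lines <- c(lines, sprintf('<%s> <%s> "%s" .',
                            onto_uri(ont$acronym, ont$classes), .RDFS_LABEL,
                            nt_escape(unname(ont$labels[ont$classes]))))
  for (cl in names(ont$synonyms)) {
    syns <- ont$synonyms[[cl]]
    if (length(syns) > 0) {
      lines <- c(lines, sprintf('<%s> <%s> "%s" .',
                                onto_uri(ont$acronym, cl), .SYNONYM_PRED,
                                nt_escape(syns)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

parse_nt_lines <- function(lines, path = "<ntriples>") {
  lines <- lines[nzchar(trimws(lines))]
  pat <- '^<([^>]*)>\\s+<([^>]*)>\\s+(?:<([^>]*)>|"((?:[^"\\\\]|\\\\.)*)")\\s*\\.\\s*$'
  m <- regmatches(lines, regexec(pat, lines))
  bad <- which(vapply(m, length, 1L) == 0)
  if (length(bad) > 0) {
    stop(sprintf("malformed N-Triples line %d in %s: %s",
                 bad[1], path, lines[bad[1]]), call. = FALSE)
  }
  data.frame(subject = vapply(m, `[`, "", 2),
             predicate = vapply(m, `[`, "", 3),
             object_uri = vapply(m, `[`, "", 4),
             object_lit = nt_unescape(vapply(m, `[`, "", 5)),
             stringsAsFactors = FALSE)
}

strip_onto_uri <- function(uri) sub("^urn:onto:[^:]+:", "", uri)
uri_acronym <- function(uri) sub("^urn:onto:([^:]+):.*$", "\\1", uri)

#' Read a toy ontology from N-Triples
#'
#' Inverse of [write_ontology_ntriples()]. Subjects/objects with unknown
#' predicates are rejected; the acronym is recovered from the class URIs
#' unless given.
#'
#' @param path N-Triples file.
#' @param acronym Optional acronym override.
#' @return A [toy_ontology()].
#' @export
read_ontology_ntriples <- function(path, acronym = NULL) {
  tr <- parse_nt_lines(readLines(path), path)
  if (is.null(acronym)) acronym <- uri_acronym(tr$subject[1])
  sub_id <- strip_onto_uri(tr$subject)
  is_sub <- tr$predicate == .RDFS_SUBCLASS
  is_lab <- tr$predicate == .RDFS_LABEL
  is_syn <- tr$predicate == .SYNONYM_PRED
  edges <- data.frame(child = sub_id[is_sub],
                      parent = strip_onto_uri(tr$object_uri[is_sub]),
                      stringsAsFactors = FALSE)
  labels <- tr$object_lit[is_lab]
  names(labels) <- sub_id[is_lab]
  synonyms <- split(tr$object_lit[is_syn], sub_id[is_syn])
  classes <- sort(unique(c(sub_id[is_lab], edges$child, edges$parent)))
  toy_ontology(acronym, classes, labels, synonyms, edges)
}

#' Write / read a subclass edge list as two-column TSV
#'
#' The TSV carries structure only (child, parent); labels default to the
#' identifiers on read unless a `labels_path` TSV (class, label) is supplied.
#'
#' @param ont A [toy_ontology()].
#' @param path Edge-list TSV path.
#' @param labels_path Optional labels TSV path.
#' @return `path`, invisibly (writer); a [toy_ontology()] (reader).
#' @export
write_ontology_tsv <- function(ont, path, labels_path = NULL) {
  utils::write.table(ont$subclass_edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(class = ont$classes, label = unname(ont$labels[ont$classes])),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ontology_tsv
#' @param acronym Acronym for the ontology read from TSV.
#' @export
read_ontology_tsv <- function(path, acronym, labels_path = NULL) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character")
  classes <- sort(unique(c(edges$child, edges$parent)))
  if (!is.null(labels_path)) {
    lt <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                            colClasses = "character")
    labels <- lt$label
    names(labels) <- lt$class
    classes <- sort(unique(c(classes, lt$class)))
  } else {
    labels <- classes
    names(labels) <- classes
  }
  toy_ontology(acronym, classes, labels, list(), edges)
}
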