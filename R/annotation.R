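# Semantic annotation: map cleaned clinical terms and codes to ontology
# classes. Free text goes through an in-process lexical index (token TF-IDF
# retrieval of the top-k candidate classes, then selection of the candidate
# whose label is closest in Levenshtein distance); coded vocabularies are
# resolved by direct identifier lookup.

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

tokenize <- function(x) strsplit(normalize_text(x), " ", fixed = TRUE)

#' Build a lexical term index over an ontology
#'
#' One entry per primary label and per synonym, mapping normalized text
#' (case-folded, punctuation stripped, whitespace collapsed) to the class it
#' names. When two classes share a text, the entry resolves to the
#' lexicographically smallest class identifier; duplicate primary labels
#' raise a warning, not an error.
#'
#' @param ontology A [toy_ontology()].
#' @return A `term_index`: entry texts, their classes, token sets, and
#'   inverse-document-frequency weights for retrieval.
#' @export
build_term_index <- function(ontology) {
  assert_that(all(nzchar(ontology$labels)), "ontology labels must be non-empty")
  texts <- unname(ontology$labels[ontology$classes])
  classes <- ontology$classes
  if (anyDuplicated(normalize_text(texts))) {
    warning("duplicate primary labels across classes; ",
            "entries resolve to the smallest class identifier")
  }
  for (cl in names(ontology$synonyms)) {
    syns <- ontology$synonyms[[cl]]
    texts <- c(texts, syns)
    classes <- c(classes, rep(cl, length(syns)))
  }
  norm <- normalize_text(texts)
  # collision rule: smallest class identifier wins per normalized text
  ord <- order(norm, classes)
  norm <- norm[ord]; classes <- classes[ord]; texts <- texts[ord]
  keep <- !duplicated(norm)
  norm <- norm[keep]; classes <- classes[keep]; texts <- texts[keep]

  toks <- strsplit(norm, " ", fixed = TRUE)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  df <- table(factor(unlist(lapply(toks, unique), use.names = FALSE),
                     levels = vocab))
  idf <- log((length(norm) + 1) / (as.numeric(df) + 1)) + 1
  names(idf) <- vocab
  postings <- split(rep(seq_along(norm), lengths(toks)),
                    unlist(toks, use.names = FALSE))
  entry_norm <- vapply(toks, function(tt)
    sqrt(sum(idf[unique(tt)]^2)), 0)
  structure(list(acronym = ontology$acronym, text = norm, class_id = classes,
                 tokens = toks, idf = idf, postings = postings,
                 entry_norm = entry_norm),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat(sprintf("term_index '%s': %d entries, %d tokens\n", x$acronym,
              length(x$text), length(x$idf)))
  invisible(x)
}

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute edit distance.
#'
#' @param a,b Character scalars or vectors (recycled pairwise).
#' @return Non-negative integer distance(s).
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b, costs = c(insertions = 1, deletions = 1,
                                    substitutions = 1))
  if (length(a) == length(b) && length(a) > 1) diag(d) else as.integer(d)
}

#' Annotate a free-text term against a term index
#'
#' Retrieval-then-selection: the `k` best entries by token TF-IDF cosine
#' score are retrieved, and among them the class whose entry text has the
#' smallest Levenshtein distance to the (normalized) term is selected. Ties
#' break toward the lexicographically smallest class identifier. A term
#' sharing no token with any entry is unannotated (`NA`).
#'
#' @param term Non-empty character scalar.
#' @param index A [build_term_index()] result.
#' @param k Number of retrieved candidates (default 6).
#' @param max_distance Optional cutoff on the winning Levenshtein distance;
#'   `Inf` (default) imposes none.
#' @return Character class identifier, or `NA_character_`; attribute
#'   `diagnostics` holds the candidate table.
#' @export
annotate_term <- function(term, index, k = 6, max_distance = Inf) {
  assert_that(is.character(term) && length(term) == 1 && !is.na(term) &&
                nzchar(trimws(term)), "term must be a non-empty string")
  assert_that(k >= 1, "k must be >= 1")
  q <- normalize_text(term)
  qt <- unique(strsplit(q, " ", fixed = TRUE)[[1]])
  qt <- qt[qt %in% names(index$idf)]
  if (length(qt) == 0) return(structure(NA_character_, diagnostics = NULL))
  cand <- unique(unlist(index$postings[qt], use.names = FALSE))
  qnorm <- sqrt(sum(index$idf[qt]^2))
  score <- vapply(cand, function(i) {
    shared <- intersect(qt, index$tokens[[i]])
    sum(index$idf[shared]^2) / (qnorm * index$entry_norm[i])
  }, 0)
  ord <- order(-score, index$text[cand])
  top <- cand[ord][seq_len(min(k, length(cand)))]
  dist <- levenshtein(rep(q, length(top)), index$text[top])
  sel <- order(dist, index$class_id[top])[1]
  diag <- data.frame(class_id = index$class_id[top], text = index$text[top],
                     score = score[ord][seq_along(top)], distance = dist,
                     stringsAsFactors = FALSE)
  if (dist[sel] > max_distance) {
    return(structure(NA_character_, diagnostics = diag))
  }
  structure(index$class_id[top][sel], diagnostics = diag)
}

#' Annotate many terms with caching over unique terms
#'
#' @param terms Character vector.
#' @inheritParams annotate_term
#' @return Named character vector (term -> class id or `NA`).
#' @export
annotate_terms <- function(terms, index, k = 6, max_distance = Inf) {
  uni <- unique(terms)
  hit <- vapply(uni, function(t) {
    if (is.na(t) || !nzchar(trimws(t)) || !grepl("[[:alnum:]]", t)) {
      NA_character_
    } else {
      as.character(annotate_term(t, index, k, max_distance))
    }
  }, "")
  stats::setNames(hit[match(terms, uni)], terms)
}

#' Ontology coverage of a term set
#'
#' Fraction of distinct terms receiving an annotation against the ontology's
#' index — a local surrogate for ontology-recommender coverage ranking.
#'
#' @param terms Non-empty character vector of terms.
#' @param ontology A [toy_ontology()] (or a prebuilt [build_term_index()]).
#' @inheritParams annotate_term
#' @return Fraction in \[0, 1\].
#' @export
coverage_score <- function(terms, ontology, k = 6, max_distance = Inf) {
  assert_that(length(terms) >= 1, "terms must be non-empty")
  index <- if (inherits(ontology, "term_index")) ontology
           else build_term_index(ontology)
  hits <- annotate_terms(unique(terms), index, k, max_distance)
  mean(!is.na(hits))
}

annotation_frame <- function(stay_id = integer(), feature_type = character(),
                             ontology = character(), class_id = character()) {
  data.frame(stay_id = stay_id, feature_type = feature_type,
             ontology = ontology, class_id = class_id,
             stringsAsFactors = FALSE)
}

#' Annotate coded features by direct identifier lookup
#'
#' Final diagnoses and procedures resolve their (formatted) ICD9-like codes
#' against the diagnosis/procedure ontology, labs their LOINC-like codes, and
#' prescriptions map NDC-like codes through the supplied lookup table into
#' the drug ontology. Unmapped codes are reported, not dropped silently.
#'
#' @param stays Stays data frame with formatted codes (see
#'   [prepare_cohort()]).
#' @param ontologies Named list of [toy_ontology()] (the multi-ontology
#'   suite).
#' @param ndc_table Data frame `ndc`, `class_id`; required when prescriptions
#'   carry NDC codes.
#' @return List `annotations` (stay_id, feature_type, ontology, class_id) and
#'   `unmatched` (stay_id, feature_type, term).
#' @export
map_codes <- function(stays, ontologies, ndc_table = NULL) {
  roles <- ontology_roles(ontologies)
  ann <- list(); unm <- list()
  add <- function(sid, ft, ont_name, ids, raw) {
    ok <- ids %in% ontologies[[ont_name]]$classes
    ann[[length(ann) + 1]] <<- annotation_frame(
      rep(sid, sum(ok)), rep(ft, sum(ok)), rep(ont_name, sum(ok)), ids[ok])
    if (any(!ok)) {
      unm[[length(unm) + 1]] <<- data.frame(
        stay_id = rep(sid, sum(!ok)), feature_type = rep(ft, sum(!ok)),
        term = raw[!ok], stringsAsFactors = FALSE)
    }
  }
  has_ndc <- any(vapply(stays$prescription_entries, function(d)
    any(nzchar(d$ndc)), TRUE))
  if (has_ndc && is.null(ndc_table)) {
    stop("NDC codes present but no ndc_table supplied", call. = FALSE)
  }
  ndc_map <- if (!is.null(ndc_table)) {
    stats::setNames(ndc_table$class_id, ndc_table$ndc)
  } else character(0)
  for (i in seq_len(nrow(stays))) {
    sid <- stays$stay_id[i]
    d <- stays$final_dx_entries[[i]]
    if (nrow(d) > 0) add(sid, "final_dx", roles[["final_dx"]], d$code, d$code)
    d <- stays$procedure_entries[[i]]
    if (nrow(d) > 0) add(sid, "procedures", roles[["procedures"]], d$code,
                         d$code)
    d <- stays$lab_entries[[i]]
    if (nrow(d) > 0) add(sid, "labs", roles[["labs"]], d$code, d$code)
    d <- stays$prescription_entries[[i]]
    if (nrow(d) > 0) {
      ids <- ifelse(d$ndc %in% names(ndc_map), ndc_map[d$ndc], NA_character_)
      ok <- !is.na(ids)
      add(sid, "prescriptions", roles[["prescriptions"]],
          ifelse(ok, ids, ""), d$ndc)
    }
  }
  list(annotations = do.call(rbind, c(list(annotation_frame()), ann)),
       unmatched = do.call(rbind, c(list(data.frame(
         stay_id = integer(), feature_type = character(), term = character(),
         stringsAsFactors = FALSE)), unm)))
}

#' Annotate a cohort under the single- or multi-ontology scenario
#'
#' Single-ontology scenario: the textual labels of every annotated feature
#' type (initial diagnoses, lab labels, drug names, final diagnosis and
#' procedure labels) are matched against one general ontology via
#' [annotate_term()]. Multi-ontology scenario: initial diagnoses are matched
#' by text against the general ontology, while labs, final diagnoses,
#' procedures and prescriptions resolve by code via [map_codes()]. The
#' annotation table is de-duplicated and sorted, so identical inputs yield
#' byte-identical TSV exports.
#'
#' @param stays Prepared stays data frame.
#' @param ontologies Named list of [toy_ontology()].
#' @param scenario `"single"` or `"multi"`.
#' @param ndc_table NDC lookup table for the multi-ontology scenario.
#' @param k Retrieval depth for text annotation.
#' @return List `annotations`, `unmatched` (as in [map_codes()]).
#' @export
annotate_cohort <- function(stays, ontologies,
                            scenario = c("single", "multi"),
                            ndc_table = NULL, k = 6) {
  scenario <- match.arg(scenario)
  if (inherits(ontologies, "toy_ontology")) ontologies <- list(ontologies)
  acr <- vapply(ontologies, function(o) o$acronym, "")
  if (is.null(names(ontologies)) || any(!nzchar(names(ontologies)))) {
    names(ontologies) <- acr
  }
  ann <- list(); unm <- list()
  text_annotate <- function(ft, texts_per_stay, ont_name, index) {
    sid <- rep(stays$stay_id, lengths(texts_per_stay))
    txt <- unlist(texts_per_stay, use.names = FALSE)
    if (length(txt) == 0) return()
    hit <- annotate_terms(txt, index, k)
    ok <- !is.na(hit)
    ann[[length(ann) + 1]] <<- annotation_frame(
      sid[ok], rep(ft, sum(ok)), rep(ont_name, sum(ok)), unname(hit[ok]))
    if (any(!ok)) {
      unm[[length(unm) + 1]] <<- data.frame(
        stay_id = sid[!ok], feature_type = rep(ft, sum(!ok)), term = txt[!ok],
        stringsAsFactors = FALSE)
    }
  }
  if (scenario == "single") {
    ont_name <- names(ontologies)[1]
    index <- build_term_index(ontologies[[ont_name]])
    text_annotate("initial_dx", stays$initial_dx_texts, ont_name, index)
    text_annotate("labs", lapply(stays$lab_entries, `[[`, "label"),
                  ont_name, index)
    text_annotate("prescriptions",
                  lapply(stays$prescription_entries, `[[`, "drug"),
                  ont_name, index)
    text_annotate("final_dx", lapply(stays$final_dx_entries, `[[`, "label"),
                  ont_name, index)
    text_annotate("procedures", lapply(stays$procedure_entries, `[[`, "label"),
                  ont_name, index)
  } else {
    roles <- ontology_roles(ontologies)
    index <- build_term_index(ontologies[[roles[["initial_dx"]]]])
    text_annotate("initial_dx", stays$initial_dx_texts,
                  roles[["initial_dx"]], index)
    coded <- map_codes(stays, ontologies, ndc_table)
    ann[[length(ann) + 1]] <- coded$annotations
    unm[[length(unm) + 1]] <- coded$unmatched
  }
  annotations <- do.call(rbind, c(list(annotation_frame()), ann))
  annotations <- unique(annotations)
  annotations <- annotations[order(annotations$stay_id,
                                   annotations$feature_type,
                                   annotations$ontology,
                                   annotations$class_id), , drop = FALSE]
  rownames(annotations) <- NULL
  unmatched <- do.call(rbind, c(list(data.frame(
    stay_id = integer(), feature_type = character(), term = character(),
    stringsAsFactors = FALSE)), unm))
  rownames(unmatched) <- NULL
  list(annotations = annotations, unmatched = unmatched)
}

#' Write an annotation table as TSV
#'
#' Fixed column order and row sort, so equal inputs produce byte-identical
#' files.
#'
#' @param annotations Annotation data frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
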