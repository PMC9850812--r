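# Independent oracles and shared fixtures. Oracles deliberately use naive
# formulations (dynamic programming, exhaustive enumeration, pair counting)
# that share no code with the implementations they check.

# --- Levenshtein: textbook dynamic-programming table ------------------------
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n > 0 && m > 0) {
    for (i in 1:n) for (j in 1:m) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (ca[i] != cb[j]))
    }
  }
  D[n + 1, m + 1]
}

random_string <- function(max_len = 12) {
  paste(sample(c(letters[1:6], " "), sample(0:max_len, 1), replace = TRUE),
        collapse = "")
}

# --- AUROC: explicit positive-negative pair counting ------------------------
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# --- Walks: exhaustive path enumeration over a raw triple table -------------
paths_oracle <- function(triples, root, max_depth, prefix = TRUE) {
  out <- list()
  grow <- function(walk, vertex, depth) {
    nxt <- which(triples$subject == vertex)
    terminal <- length(nxt) == 0 || depth == max_depth
    if (prefix || terminal) out[[length(out) + 1]] <<- walk
    if (depth == max_depth) return()
    for (i in nxt) {
      grow(c(walk, triples$predicate[i], triples$object[i]),
           triples$object[i], depth + 1)
    }
  }
  grow(root, root, 0)
  out
}

# random multi-parent DAG ontology (acyclic by construction: parents precede
# children), plus a few annotated stays
random_dag_kg <- function(n_vertices, seed, n_stays = 3) {
  set.seed(seed)
  ids <- sprintf("V%02d", seq_len(n_vertices))
  labels <- stats::setNames(paste("node", ids), ids)
  child <- character(0); parent <- character(0)
  for (i in seq_len(n_vertices)[-1]) {
    for (p in sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))) {
      child <- c(child, ids[i]); parent <- c(parent, ids[p])
    }
  }
  ont <- toy_ontology("DAG", ids, labels, list(),
                      data.frame(child = child, parent = parent))
  ann <- data.frame(stay_id = rep(seq_len(n_stays), each = 2),
                    feature_type = "initial_dx", ontology = "DAG",
                    class_id = sample(ids, 2 * n_stays, replace = TRUE),
                    stringsAsFactors = FALSE)
  build_kg(list(ont), ann)
}

# --- shared small fixtures --------------------------------------------------
test_suite <- toy_ontology_suite(seed = 101, sizes = c(NCIT = 60, LOINC = 40,
                                                       ICD9 = 50, DRON = 30))

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_patients = 50, readmission_rate = 0.3, seed = 17)
      cache <<- generate_cohort(spec, test_suite$ontologies,
                                test_suite$ndc_table)
    }
    cache
  }
})

# one-row stays table with a configurable timeline, for labelling tests
make_stay <- function(stay_id = 1, intime = 0, outtime = 10 * 1440,
                      discharge = 15 * 1440, death = NA,
                      next_icu = NA, transfers = NULL, age = 50,
                      patient_id = stay_id) {
  s <- data.frame(patient_id = patient_id, stay_id = stay_id,
                  admission_id = stay_id, age = age, gender = "F",
                  ethnicity = "WHITE", insurance = "Private",
                  intime = intime, outtime = outtime,
                  discharge_time = discharge, death_time = death,
                  next_icu_intime = next_icu, stringsAsFactors = FALSE)
  s$ward_transfer_events <- list(
    transfers %||% data.frame(time = integer(), destination = character(),
                              stringsAsFactors = FALSE))
  s$initial_dx_texts <- list("acute test finding")
  s$final_dx_entries <- list(data.frame(code = "4019", label = "x",
                                        stringsAsFactors = FALSE))
  s$procedure_entries <- list(data.frame(code = "0331", label = "y",
                                         stringsAsFactors = FALSE))
  s$prescription_entries <- list(data.frame(drug = "z", ndc = "",
                                            stringsAsFactors = FALSE))
  s$lab_entries <- list(data.frame(label = "lab", code = "1-1",
                                   stringsAsFactors = FALSE))
  s$chart_events <- list(stats::setNames(rep(1, 3), paste0("chart_0", 1:3)))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
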