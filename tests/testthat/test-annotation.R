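mini_ontology <- function(labels, synonyms = list(), acronym = "M") {
  ids <- sprintf("%s:C%02d", acronym, seq_along(labels))
  toy_ontology(acronym, ids, stats::setNames(labels, ids), synonyms)
}

test_that("term index holds one entry per label and synonym with tie rule", {
  ont <- mini_ontology(c("alpha heart", "beta lung", "gamma liver"))
  idx <- build_term_index(ont)
  expect_length(idx$text, 3)

  ont2 <- mini_ontology(c("alpha heart", "beta lung"),
                        synonyms = list("M:C01" = c("cardiac alpha",
                                                    "heart thing")))
  idx2 <- build_term_index(ont2)
  expect_length(idx2$text, 4)
  expect_equal(sum(idx2$class_id == "M:C01"), 3)

  # shared synonym resolves to the smaller class identifier
  ont3 <- mini_ontology(c("alpha heart", "beta lung"),
                        synonyms = list("M:C02" = "shared name",
                                        "M:C01" = "shared name"))
  idx3 <- build_term_index(ont3)
  expect_equal(idx3$class_id[idx3$text == "shared name"], "M:C01")

  # duplicate primary labels warn but do not error
  ids <- c("M:C01", "M:C02")
  dup <- toy_ontology("M", ids, stats::setNames(c("same label", "same label"),
                                                ids))
  expect_warning(build_term_index(dup), "duplicate primary labels")
})

test_that("levenshtein distance matches the classic example and identities", {
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  for (s in c("", "a", "acute renal failure")) {
    expect_equal(levenshtein(s, s), 0L)
    expect_equal(levenshtein("", s), nchar(s))
  }
  set.seed(31)
  for (i in 1:50) {
    a <- random_string(); b <- random_string()
    expect_equal(levenshtein(a, b), lev_oracle(a, b))
  }
})

test_that("annotation selects the retrieved candidate at minimum distance", {
  ont <- mini_ontology(c("acute cardiac arrest", "chronic cardiac failure",
                         "benign lung nodule"))
  idx <- build_term_index(ont)

  hit <- annotate_term("acute cardiac arrest", idx)
  expect_equal(as.character(hit), "M:C01")
  expect_equal(attr(hit, "diagnostics")$distance[1], 0)

  expect_true(is.na(annotate_term("zzz qqq", idx)))
  expect_error(annotate_term("", idx), "non-empty")
  expect_error(annotate_term("x", idx, k = 0), "k must be")

  # deterministic across repeated calls
  t1 <- annotate_term("cardiac arest", idx)
  t2 <- annotate_term("cardiac arest", idx)
  expect_identical(as.character(t1), as.character(t2))

  # tie at equal distance: the smaller identifier wins; verify by brute force
  tie <- mini_ontology(c("red fox", "red box"))
  tidx <- build_term_index(tie)
  got <- annotate_term("red cox", tidx)
  d1 <- lev_oracle("red cox", "red fox")
  d2 <- lev_oracle("red cox", "red box")
  expect_equal(d1, d2)
  expect_equal(as.character(got), "M:C01")

  # winner is never beaten by another retrieved candidate
  set.seed(7)
  ont_big <- test_suite$ontologies$NCIT
  idx_big <- build_term_index(ont_big)
  terms <- sample(unname(ont_big$labels), 15)
  terms <- paste(terms, "x")  # perturb so distances vary
  for (tm in terms) {
    got <- annotate_term(tm, idx_big)
    diagn <- attr(got, "diagnostics")
    if (is.na(got)) next
    dwin <- min(diagn$distance)
    expect_true(all(diagn$distance >= dwin))
    expect_equal(lev_oracle(icukg:::normalize_text(tm),
                            diagn$text[which.min(diagn$distance)]), dwin)
  }
})

test_that("coverage score counts distinct annotated terms", {
  ont <- mini_ontology(c("one term", "two term", "three term", "four term"))
  expect_equal(coverage_score(unname(ont$labels), ont), 1.0)
  expect_equal(coverage_score(c("zzz", "qqq yyy"), ont), 0.0)
  expect_equal(coverage_score(c("one term", "two term", "zz", "qq"), ont), 0.5)
  expect_error(coverage_score(character(0), ont), "non-empty")
})

test_that("coverage is monotone non-decreasing under added synonyms", {
  for (seed in 1:3) {
    set.seed(seed)
    base <- generate_toy_ontology("C", 20, 2, synonyms_per_class = 0,
                                  seed = seed)
    terms <- c(sample(unname(base$labels), 5),
               paste("held out", seed), "completely different words")
    cov0 <- coverage_score(terms, base)
    richer <- base
    richer$synonyms <- stats::setNames(
      lapply(seq_along(base$classes), function(i) paste("held out", seed)),
      base$classes)[1]
    cov1 <- coverage_score(terms, richer)
    expect_gte(cov1, cov0)
  }
})

test_that("coded features resolve by lookup and misses are reported", {
  coh <- small_cohort()
  prep <- prepare_cohort(coh$stays)
  res <- map_codes(prep$stays, test_suite$ontologies, test_suite$ndc_table)
  expect_true(all(res$annotations$feature_type %in%
                    c("final_dx", "procedures", "labs", "prescriptions")))
  # every annotated class exists in its named ontology
  for (o in unique(res$annotations$ontology)) {
    cls <- res$annotations$class_id[res$annotations$ontology == o]
    expect_true(all(cls %in% test_suite$ontologies[[o]]$classes))
  }
  # a lab code outside the vocabulary lands in unmatched
  s <- prep$stays[1, ]
  s$lab_entries <- list(data.frame(label = "mystery", code = "0-0",
                                   stringsAsFactors = FALSE))
  miss <- map_codes(s, test_suite$ontologies, test_suite$ndc_table)
  expect_true("0-0" %in% miss$unmatched$term)
  # NDC codes without a table are a configuration error
  expect_error(map_codes(prep$stays, test_suite$ontologies, NULL),
               "ndc_table")
  # mixed stay: 2 labs + 1 drug -> 3 annotations across 2 ontologies
  s2 <- prep$stays[1, ]
  s2$final_dx_entries <- list(data.frame(code = character(),
                                         label = character()))
  s2$procedure_entries <- list(data.frame(code = character(),
                                          label = character()))
  s2$lab_entries <- list(data.frame(
    label = c("a", "b"),
    code = test_suite$ontologies$LOINC$classes[1:2],
    stringsAsFactors = FALSE))
  dron_first <- test_suite$ndc_table[1, ]
  s2$prescription_entries <- list(data.frame(drug = "d", ndc = dron_first$ndc,
                                             stringsAsFactors = FALSE))
  got <- map_codes(s2, test_suite$ontologies, test_suite$ndc_table)
  expect_equal(nrow(got$annotations), 3)
  expect_setequal(unique(got$annotations$ontology), c("LOINC", "DRON"))
})

test_that("both scenarios annotate every stay with usable terms", {
  coh <- small_cohort()
  prep <- prepare_cohort(coh$stays)
  multi <- annotate_cohort(prep$stays, test_suite$ontologies, "multi",
                           test_suite$ndc_table)
  expect_setequal(unique(multi$annotations$stay_id), prep$stays$stay_id)

  ncit <- list(NCIT = test_suite$ontologies$NCIT)
  coh1 <- generate_cohort(cohort_spec(n_patients = 40, seed = 23), ncit)
  prep1 <- prepare_cohort(coh1$stays)
  single <- annotate_cohort(prep1$stays, ncit, "single")
  expect_setequal(unique(single$annotations$ontology), "NCIT")
  expect_setequal(unique(single$annotations$stay_id), prep1$stays$stay_id)
  # annotation TSV export is byte-stable
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotations(single$annotations, f1)
  write_annotations(annotate_cohort(prep1$stays, ncit, "single")$annotations,
                    f2)
  expect_identical(readLines(f1), readLines(f2))
})
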