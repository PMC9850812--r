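# End-to-end experiment driver: prepare -> annotate -> build KG -> embed ->
# assemble patient vectors -> cross-validated prediction, over a grid of
# snapshot moments, annotation-ablation fractions and classifiers.

train_embedding <- function(kg, method, dimension, seed, embed_params = list()) {
  args <- c(list(kg = kg, dimension = dimension, seed = seed), embed_params)
  switch(method,
         rdf2vec = do.call(train_rdf2vec, args),
         opa2vec = do.call(train_opa2vec, args),
         transe = do.call(train_transe, args),
         stop("unknown embedding method: ", method, call. = FALSE))
}

#' Train embedding spaces for an annotated cohort
#'
#' Single-ontology scenario: one space over the joint KG. Multi-ontology
#' scenario: one space per ontology over that ontology's sub-KG (classes,
#' subclass edges, and the stay annotations landing in it), later
#' concatenated per stay.
#'
#' @param annotations Annotation data frame.
#' @param ontologies Named list of [toy_ontology()].
#' @param scenario `"single"` or `"multi"`.
#' @param method `"rdf2vec"`, `"transe"` or `"opa2vec"`.
#' @param dimension Embedding width.
#' @param seed Integer seed.
#' @param embed_params Extra arguments passed to the trainer.
#' @return An `embedding_space` (single) or named list of spaces (multi).
#' @export
train_cohort_spaces <- function(annotations, ontologies,
                                scenario = c("single", "multi"),
                                method = "rdf2vec", dimension = 300,
                                seed = 1, embed_params = list()) {
  scenario <- match.arg(scenario)
  if (inherits(ontologies, "toy_ontology")) ontologies <- list(ontologies)
  if (scenario == "single") {
    kg <- build_kg(ontologies, annotations,
                   include_labels = (method == "opa2vec"))
    train_embedding(kg, method, dimension, seed, embed_params)
  } else {
    spaces <- lapply(names(ontologies), function(o) {
      sub <- annotations[annotations$ontology == o, , drop = FALSE]
      kg <- build_kg(ontologies[o], sub,
                     include_labels = (method == "opa2vec"))
      train_embedding(kg, method, dimension,
                      derive_seed(seed, match(o, names(ontologies))),
                      embed_params)
    })
    names(spaces) <- names(ontologies)
    spaces
  }
}

#' Run a readmission prediction experiment
#'
#' Cleans and labels the stays, annotates them under the chosen scenario,
#' trains one embedding space (or one per ontology), and evaluates the
#' requested classifiers with stratified k-fold cross-validation over the
#' grid of snapshot moments and annotation-ablation fractions. Reports
#' per-fold metrics, mean and standard deviation per configuration, averaged
#' test-fold confusion matrices, and pairwise Kruskal-Wallis p-values
#' between configurations per model and metric.
#'
#' @param stays Raw stays data frame (simulator layout).
#' @param ontologies Named list of [toy_ontology()].
#' @param scenario `"single"` or `"multi"`.
#' @param moments Snapshot moments to evaluate.
#' @param method Embedding method.
#' @param models Classifiers, subset of `c("LR", "RF", "NB", "SVM")`.
#' @param dimension Embedding width.
#' @param k Cross-validation folds.
#' @param seed Master seed (folds, embedding, ablation draws).
#' @param ndc_table NDC lookup table (multi-ontology scenario).
#' @param keep_fractions Annotation fractions for the ablation grid.
#' @param permute_labels Permute outcome labels before evaluation (null
#'   check).
#' @param window_days Readmission window.
#' @param embed_params Extra trainer arguments.
#' @return A `readmission_report` list: `metrics`, `summary`, `confusion`,
#'   `kruskal`, `annotations`, `unmatched`, `kg_stats`, `spaces`, `labels`.
#' @export
run_experiment <- function(stays, ontologies,
                           scenario = c("single", "multi"),
                           moments = "in_icu", method = "rdf2vec",
                           models = "RF", dimension = 300, k = 5, seed = 1,
                           ndc_table = NULL, keep_fractions = 1,
                           permute_labels = FALSE, window_days = 30,
                           embed_params = list()) {
  scenario <- match.arg(scenario)
  assert_that(all(moments %in% c("pre_icu", "in_icu", "post_icu")),
              "unknown snapshot moment in config")
  assert_that(all(models %in% c("LR", "RF", "NB", "SVM")),
              "unknown model in config")
  prep <- prepare_cohort(stays, window_days)
  ann <- annotate_cohort(prep$stays, ontologies, scenario, ndc_table)
  spaces <- train_cohort_spaces(ann$annotations, ontologies, scenario,
                                method, dimension, seed, embed_params)
  kg <- build_kg(ontologies, ann$annotations)
  y_all <- as.integer(prep$labels$label == "positive")
  if (permute_labels) {
    y_all <- with_local_seed(derive_seed(seed, 991), sample(y_all))
  }
  names(y_all) <- as.character(prep$stays$stay_id)

  metrics <- list()
  for (moment in moments) {
    for (frac in keep_fractions) {
      ann_use <- ablate_annotations(ann$annotations, frac,
                                    derive_seed(seed, round(1000 * frac)))
      X <- assemble_patient_vectors(prep$stays, ann_use, spaces, moment)
      y <- unname(y_all[as.character(attr(X, "stay_ids"))])
      for (model in models) {
        cv <- run_cv(X, y, model, k, seed)
        cv$moment <- moment
        cv$keep_fraction <- frac
        metrics[[length(metrics) + 1]] <- cv
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics$config <- paste(metrics$moment, metrics$keep_fraction, sep = "|")

  agg <- function(v, f) stats::aggregate(v, by = list(
    config = metrics$config, model = metrics$model), FUN = f)
  summary <- agg(metrics$auroc, mean)
  names(summary)[3] <- "auroc_mean"
  summary$auroc_sd <- agg(metrics$auroc, stats::sd)$x
  summary$auprc_mean <- agg(metrics$auprc, mean)$x
  summary$auprc_sd <- agg(metrics$auprc, stats::sd)$x

  confusion <- stats::aggregate(metrics[c("tn", "fp", "fn", "tp")],
                                by = list(config = metrics$config,
                                          model = metrics$model), FUN = mean)

  kruskal <- NULL
  configs <- unique(metrics$config)
  if (length(configs) > 1) {
    rows <- list()
    for (model in unique(metrics$model)) {
      for (i in seq_along(configs)) for (j in seq_along(configs)) {
        if (i >= j) next
        mi <- metrics[metrics$model == model & metrics$config == configs[i], ]
        mj <- metrics[metrics$model == model & metrics$config == configs[j], ]
        for (metric in c("auroc", "auprc")) {
          kw <- suppressWarnings(compare_kruskal(mi[[metric]], mj[[metric]]))
          rows[[length(rows) + 1]] <- data.frame(
            model = model, config_a = configs[i], config_b = configs[j],
            metric = metric, statistic = kw[["statistic"]],
            p.value = kw[["p.value"]], stringsAsFactors = FALSE)
        }
      }
    }
    kruskal <- do.call(rbind, rows)
  }

  structure(list(metrics = metrics, summary = summary, confusion = confusion,
                 kruskal = kruskal, annotations = ann$annotations,
                 unmatched = ann$unmatched, kg_stats = kg_stats(kg),
                 spaces = spaces, labels = prep$labels,
                 exclusion_report = prep$exclusion_report),
            class = "readmission_report")
}

#' @export
print.readmission_report <- function(x, ...) {
  cat("readmission_report\n")
  cat(sprintf("  KG: %d triples, %d subjects, %d predicates\n",
              x$kg_stats$triples, x$kg_stats$subjects, x$kg_stats$predicates))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  [%s] %s: AUROC %.3f +/- %.3f, AUPRC %.3f +/- %.3f\n",
                s$config[i], s$model[i], s$auroc_mean[i], s$auroc_sd[i],
                s$auprc_mean[i], s$auprc_sd[i]))
  }
  invisible(x)
}
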