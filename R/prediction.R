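# Patient vectors and readmission prediction: one-hot demographics +
# median-imputed chart events + aggregated KG-embedding block, evaluated with
# four classical classifiers under stratified five-fold cross-validation.

#' One-hot encode demographics
#'
#' Fixed level sets (taken from the full cohort) keep the encoding identical
#' across folds; the block is the one-hot gender/ethnicity/insurance columns
#' plus age, so its width is g + e + i + 1.
#'
#' @param stays Stays data frame.
#' @param levels Optional list with `gender`, `ethnicity`, `insurance` level
#'   vectors.
#' @return Numeric matrix, one row per stay.
#' @export
encode_demographics <- function(stays, levels = NULL) {
  levels <- levels %||% list(gender = sort(unique(stays$gender)),
                             ethnicity = sort(unique(stays$ethnicity)),
                             insurance = sort(unique(stays$insurance)))
  onehot <- function(x, lv, prefix) {
    m <- outer(x, lv, `==`) * 1
    colnames(m) <- paste0(prefix, "_", gsub(" ", "_", lv))
    m
  }
  cbind(onehot(stays$gender, levels$gender, "gender"),
        onehot(stays$ethnicity, levels$ethnicity, "ethnicity"),
        onehot(stays$insurance, levels$insurance, "insurance"),
        age = stays$age)
}

#' Assemble patient vectors for a snapshot moment
#'
#' Concatenates the blocks available at the moment: demographics (always),
#' chart events (in/post-ICU; raw, possibly with missing values — imputation
#' happens inside cross-validation with training-fold medians), and the
#' embedding block aggregated from the annotations of the feature types
#' visible at the moment. Unavailable blocks are omitted, not zeroed.
#'
#' @param stays Prepared stays data frame.
#' @param annotations Annotation data frame.
#' @param space `embedding_space` for the single-ontology scenario, or a
#'   named list of spaces (one per ontology) for the multi-ontology scenario;
#'   multi-ontology blocks are concatenated in `ontology_order`.
#' @param moment `"pre_icu"`, `"in_icu"` or `"post_icu"`.
#' @param ontology_order Block order for the multi-ontology case.
#' @param chart_medians Optional per-feature medians used to impute missing
#'   chart values immediately (leave `NULL` to defer to [run_cv()]).
#' @return Numeric matrix with attribute `layout` (named index slices) and
#'   `stay_ids`; stays ineligible for the moment (no initial diagnosis at
#'   pre-ICU) are dropped.
#' @export
assemble_patient_vectors <- function(stays, annotations, space, moment,
                                     ontology_order = NULL,
                                     chart_medians = NULL) {
  snap <- snapshot_split(stays, moment)
  stays <- stays[stays$stay_id %in% snap$stay_ids, , drop = FALSE]
  ann <- annotations[annotations$feature_type %in% snap$feature_types, ,
                     drop = FALSE]
  blocks <- list(demographics = encode_demographics(stays))
  if ("chart_events" %in% snap$feature_types) {
    chart <- do.call(rbind, stays$chart_events)
    if (!is.null(chart_medians)) {
      for (j in seq_len(ncol(chart))) {
        chart[is.na(chart[, j]), j] <- chart_medians[j]
      }
    }
    blocks$chart <- chart
  }
  if (inherits(space, "embedding_space")) {
    blocks$embedding <- embed_stays(ann, space, stays$stay_id)
  } else {
    ontology_order <- ontology_order %||% names(space)
    per <- lapply(ontology_order, function(o)
      embed_stays(ann, space[[o]], stays$stay_id, ontology = o))
    names(per) <- ontology_order
    blocks$embedding <- concat_multi_ontology(per, ontology_order)
  }
  X <- do.call(cbind, blocks)
  ends <- cumsum(vapply(blocks, ncol, 1L))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  layout <- Map(function(s, e) s:e, starts, ends)
  names(layout) <- names(blocks)
  attr(X, "layout") <- layout
  attr(X, "stay_ids") <- stays$stay_id
  X
}

#' Threshold-free classifier metrics
#'
#' AUROC is the probability that a random positive outscores a random
#' negative, ties counted one half (computed from the rank-sum identity).
#' AUPRC is the area under the precision-recall curve by right-continuous
#' step interpolation: the sum of precision times recall increments in
#' descending score order, score ties grouped.
#'
#' @param scores Continuous classifier scores (higher = more positive).
#' @param labels 0/1 (or logical) true labels containing both classes.
#' @return List `auroc`, `auprc`.
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0,
              "metrics undefined: labels must contain both classes")
  r <- rank(scores)  # average ranks handle ties as half-wins
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  grp_last <- c(diff(s) != 0, TRUE)  # last index of each tied score block
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1 - y)[grp_last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin, so fold prevalences match the cohort within one instance
stratified_folds <- function(labels, k, seed) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(min(table(labels)) >= k,
              "k exceeds the size of the minority class")
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# median imputation where the statistic comes from the training rows only:
# the test matrix never influences the fill value
impute_with_train_medians <- function(X_train, X_test, cols) {
  for (j in cols) {
    med <- stats::median(X_train[, j], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    X_train[is.na(X_train[, j]), j] <- med
    X_test[is.na(X_test[, j]), j] <- med
  }
  list(train = X_train, test = X_test)
}

fit_and_score <- function(model, X_train, y_train, X_test, seed) {
  if (model == "LR") {
    df_tr <- as.data.frame(X_train)
    fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                       data = cbind(df_tr, y = y_train)))
    score <- suppressWarnings(
      stats::predict(fit, as.data.frame(X_test), type = "response"))
    list(score = as.numeric(score), threshold = 0.5)
  } else if (model == "RF") {
    colnames(X_train) <- colnames(X_test) <-
      paste0("f", seq_len(ncol(X_train)))
    fit <- ranger::ranger(x = X_train, y = factor(y_train, levels = c(0, 1)),
                          probability = TRUE, num.trees = 100,
                          seed = seed, num.threads = 1)
    p <- stats::predict(fit, X_test, num.threads = 1)$predictions[, "1"]
    list(score = as.numeric(p), threshold = 0.5)
  } else if (model == "NB") {
    keep <- apply(X_train, 2, stats::sd) > 0
    fit <- e1071::naiveBayes(x = as.data.frame(X_train[, keep, drop = FALSE]),
                             y = factor(y_train, levels = c(0, 1)))
    p <- stats::predict(fit, as.data.frame(X_test[, keep, drop = FALSE]),
                        type = "raw")[, "1"]
    list(score = as.numeric(p), threshold = 0.5)
  } else if (model == "SVM") {
    fit <- suppressWarnings(
      e1071::svm(x = X_train, y = factor(y_train, levels = c(0, 1)),
                 kernel = "radial", cost = 1, scale = TRUE))
    dv_tr <- attr(stats::predict(fit, X_train, decision.values = TRUE),
                  "decision.values")[, 1]
    flip <- mean(dv_tr[y_train == 1]) < mean(dv_tr[y_train == 0])
    dv <- attr(stats::predict(fit, X_test, decision.values = TRUE),
               "decision.values")[, 1]
    list(score = as.numeric(if (flip) -dv else dv), threshold = 0)
  } else {
    stop("unknown model: ", model, call. = FALSE)
  }
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Trains on k-1 folds and scores the held-out fold with continuous scores
#' (class probabilities; decision values for the SVM). Missing chart values
#' are imputed with training-fold medians only (no leakage). No
#' hyperparameter optimization is applied.
#'
#' @param X Feature matrix with optional `layout` attribute (its `chart`
#'   slice is median-imputed per fold).
#' @param y 0/1 labels.
#' @param model `"LR"`, `"RF"`, `"NB"` or `"SVM"`.
#' @param k Folds (default 5).
#' @param seed Integer seed controlling the fold partition and any model
#'   randomness.
#' @return Data frame of fold results: `model`, `fold`, `auroc`, `auprc`,
#'   `tn`, `fp`, `fn`, `tp` (confusion at probability 0.5 / decision value
#'   0).
#' @export
run_cv <- function(X, y, model = c("LR", "RF", "NB", "SVM"), k = 5,
                   seed = 1) {
  model <- match.arg(model)
  y <- as.integer(y)
  fold <- stratified_folds(y, k, seed)
  layout <- attr(X, "layout")
  chart_cols <- layout$chart
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    X_train <- X[tr, , drop = FALSE]; X_test <- X[te, , drop = FALSE]
    if (!is.null(chart_cols)) {
      imp <- impute_with_train_medians(X_train, X_test, chart_cols)
      X_train <- imp$train; X_test <- imp$test
    }
    fs <- fit_and_score(model, X_train, y[tr], X_test,
                        seed = derive_seed(seed, f))
    m <- compute_metrics(fs$score, y[te])
    pred <- as.integer(fs$score > fs$threshold)
    out[[f]] <- data.frame(model = model, fold = f, auroc = m$auroc,
                           auprc = m$auprc,
                           tn = sum(pred == 0 & y[te] == 0),
                           fp = sum(pred == 1 & y[te] == 0),
                           fn = sum(pred == 0 & y[te] == 1),
                           tp = sum(pred == 1 & y[te] == 1),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Two-sample Kruskal-Wallis comparison of fold metrics
#'
#' Rank-based H statistic with the chi-square (df = 1) approximation and tie
#' correction, as used to compare per-fold AUROC/AUPRC values between two
#' configurations. Identical constant samples degenerate; a warning is
#' raised and p reported as 1.
#'
#' @param metric_values_a,metric_values_b Non-empty numeric vectors.
#' @return Named vector `statistic`, `p.value`.
#' @export
compare_kruskal <- function(metric_values_a, metric_values_b) {
  assert_that(length(metric_values_a) > 0 && length(metric_values_b) > 0,
              "both samples must be non-empty")
  x <- c(metric_values_a, metric_values_b)
  if (length(unique(x)) == 1) {
    warning("degenerate comparison: all metric values identical")
    return(c(statistic = 0, p.value = 1))
  }
  g <- factor(rep(c("a", "b"), c(length(metric_values_a),
                                 length(metric_values_b))))
  kt <- stats::kruskal.test(x, g)
  c(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Randomly thin a cohort's annotations
#'
#' Per stay, a uniform sample of `ceiling(keep_fraction * n)` annotations is
#' kept (never emptying a stay), deterministically under `seed` — the
#' annotation-completeness ablation.
#'
#' @param annotations Annotation data frame.
#' @param keep_fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Thinned annotation data frame (original row order preserved).
#' @export
ablate_annotations <- function(annotations, keep_fraction, seed = 1) {
  assert_that(is_scalar_number(keep_fraction) && keep_fraction > 0 &&
                keep_fraction <= 1, "keep_fraction must lie in (0, 1]")
  if (keep_fraction == 1) return(annotations)
  with_local_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(annotations)),
                                annotations$stay_id), function(idx) {
      sort(idx[sample.int(length(idx), ceiling(keep_fraction * length(idx)))])
    }), use.names = FALSE)
    out <- annotations[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
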