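test_that("AUROC and AUPRC follow their probabilistic definitions", {
  m <- compute_metrics(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(m$auroc, 0.5)
  expect_equal(compute_metrics(c(0.9, 0.8, 0.2, 0.1),
                               c(1, 1, 0, 0))$auroc, 1.0)
  expect_equal(compute_metrics(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))$auroc, 0.5)
  expect_error(compute_metrics(c(0.1, 0.2), c(1, 1)), "both classes")

  # pair-counting oracle over many small inputs, with heavy score ties
  set.seed(55)
  for (rep in 1:150) {
    n <- sample(2:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(compute_metrics(scores, labels)$auroc,
                 auroc_oracle(scores, labels), tolerance = 1e-12)
  }

  # AUPRC sanity: perfect ranking gives 1, reversal is poor
  expect_equal(compute_metrics(c(0.9, 0.8, 0.2), c(1, 1, 0))$auprc, 1)
  expect_lt(compute_metrics(c(0.1, 0.9), c(1, 0))$auprc, 1)
})

test_that("stratified folds partition stays and preserve prevalence", {
  y <- c(rep(1, 23), rep(0, 77))
  fold <- icukg:::stratified_folds(y, 5, seed = 2)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 100)
  pos_per_fold <- tapply(y, fold, sum)
  expect_lte(diff(range(pos_per_fold)), 1)  # prevalence within one instance
  n_per_fold <- table(fold)
  expect_lte(diff(range(n_per_fold)), 2)  # one residue per class
  expect_error(icukg:::stratified_folds(c(1, 0, 0, 0, 0, 0), 5, 1),
               "minority")
})

test_that("cross-validation recovers a separable signal and stays honest", {
  set.seed(9)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(f1 = y * 4 + rnorm(n, 0, 0.1), f2 = rnorm(n))
  for (mod in c("LR", "RF", "NB", "SVM")) {
    cv <- run_cv(X, y, mod, k = 5, seed = 3)
    expect_equal(nrow(cv), 5)
    expect_gt(mean(cv$auroc), 0.95)
    expect_equal(cv$tn + cv$fp + cv$fn + cv$tp,
                 as.integer(table(icukg:::stratified_folds(y, 5, 3))),
                 ignore_attr = TRUE)
  }
  # determinism: identical fold metrics on a second run
  cv1 <- run_cv(X, y, "RF", k = 5, seed = 3)
  cv2 <- run_cv(X, y, "RF", k = 5, seed = 3)
  expect_identical(cv1, cv2)
})

test_that("chart imputation draws its medians from training rows only", {
  X_train <- cbind(a = c(1, 2, 3, NA, 100), b = 1:5)
  X_test <- cbind(a = c(NA, 50), b = 1:2)
  imp <- icukg:::impute_with_train_medians(X_train, X_test, cols = 1)
  expect_equal(unname(imp$train[4, "a"]), 2.5)  # median of 1,2,3,100
  expect_equal(unname(imp$test[1, "a"]), 2.5)
  # moving a test value never changes the fill
  X_test2 <- cbind(a = c(NA, 1e6), b = 1:2)
  imp2 <- icukg:::impute_with_train_medians(X_train, X_test2, cols = 1)
  expect_equal(imp2$test[1, "a"], imp$test[1, "a"])
  # all-missing training column falls back to zero
  Xt <- cbind(a = c(NA_real_, NA), b = c(1, 2))
  imp3 <- icukg:::impute_with_train_medians(Xt, Xt, cols = 1)
  expect_equal(unname(imp3$train[, "a"]), c(0, 0))
})

test_that("Kruskal-Wallis comparison matches the rank-sum formula", {
  kw_oracle <- function(a, b) {  # no-ties rank formula
    x <- c(a, b); r <- rank(x); N <- length(x)
    Ra <- mean(r[seq_along(a)]); Rb <- mean(r[-seq_along(a)])
    H <- 12 / (N * (N + 1)) *
      (length(a) * (Ra - (N + 1) / 2)^2 + length(b) * (Rb - (N + 1) / 2)^2)
    c(H = H, p = stats::pchisq(H, 1, lower.tail = FALSE))
  }
  got <- compare_kruskal(1:5, 6:10)
  want <- kw_oracle(1:5, 6:10)
  expect_equal(unname(got["statistic"]), unname(want["H"]), tolerance = 1e-6)
  expect_lt(abs(unname(got["p.value"]) - 0.009), 0.001)

  got2 <- compare_kruskal(c(1, 3, 5), c(2, 4, 6))
  want2 <- kw_oracle(c(1, 3, 5), c(2, 4, 6))
  expect_equal(unname(got2["statistic"]), unname(want2["H"]),
               tolerance = 1e-6)
  expect_equal(unname(got2["p.value"]), unname(want2["p"]), tolerance = 1e-6)

  expect_warning(res <- compare_kruskal(c(2, 2), c(2, 2)), "degenerate")
  expect_equal(unname(res["p.value"]), 1)
  expect_error(compare_kruskal(numeric(0), 1), "non-empty")
})

test_that("annotation ablation keeps the ceiling count per stay", {
  ann <- data.frame(stay_id = rep(c(1, 2), c(10, 1)),
                    feature_type = "labs", ontology = "O",
                    class_id = sprintf("c%02d", 1:11),
                    stringsAsFactors = FALSE)
  expect_identical(ablate_annotations(ann, 1.0, seed = 1), ann)
  half <- ablate_annotations(ann, 0.5, seed = 1)
  expect_equal(sum(half$stay_id == 1), 5)
  expect_equal(sum(half$stay_id == 2), 1)  # ceiling never empties a stay
  quarter <- ablate_annotations(ann, 0.25, seed = 1)
  expect_equal(sum(quarter$stay_id == 2), 1)
  expect_identical(ablate_annotations(ann, 0.5, seed = 1),
                   ablate_annotations(ann, 0.5, seed = 1))
  expect_error(ablate_annotations(ann, 0), "keep_fraction")
})

test_that("patient vectors assemble the blocks available at each moment", {
  coh <- small_cohort()
  prep <- prepare_cohort(coh$stays)
  ann <- annotate_cohort(prep$stays, test_suite$ontologies, "multi",
                         test_suite$ndc_table)$annotations
  spaces <- train_cohort_spaces(ann, test_suite$ontologies, "multi",
                                dimension = 8, seed = 2,
                                embed_params = list(epochs = 2))
  g <- length(unique(prep$stays$gender))
  e <- length(unique(prep$stays$ethnicity))
  i <- length(unique(prep$stays$insurance))

  Xpre <- assemble_patient_vectors(prep$stays, ann, spaces, "pre_icu")
  lay <- attr(Xpre, "layout")
  expect_named(lay, c("demographics", "embedding"))
  expect_length(lay$demographics, g + e + i + 1)
  expect_equal(ncol(Xpre), g + e + i + 1 + 4 * 8)
  # pre-ICU embedding block only sums initial-diagnosis annotations
  sid <- attr(Xpre, "stay_ids")[1]
  pre_ann <- ann[ann$stay_id == sid & ann$feature_type == "initial_dx", ]
  per <- lapply(names(spaces), function(o)
    embed_stay(pre_ann, spaces[[o]], o))
  names(per) <- names(spaces)
  expect_equal(unname(Xpre[1, lay$embedding]),
               unname(concat_multi_ontology(per, names(spaces))))

  Xin <- assemble_patient_vectors(prep$stays, ann, spaces, "in_icu")
  lay_in <- attr(Xin, "layout")
  expect_named(lay_in, c("demographics", "chart", "embedding"))
  expect_length(lay_in$chart, 17)
  # layout slices are contiguous and non-overlapping
  expect_equal(unname(unlist(lay_in)), seq_len(ncol(Xin)))

  # imputation changes nothing when nothing is missing
  full <- Xin
  full[is.na(full)] <- 1
  imp <- icukg:::impute_with_train_medians(full, full, lay_in$chart)
  expect_identical(imp$train, full)
})

test_that("an experiment report carries metrics, confusion and comparisons", {
  ncit <- list(NCIT = test_suite$ontologies$NCIT)
  coh <- generate_cohort(cohort_spec(n_patients = 60, readmission_rate = 0.3,
                                     seed = 29), ncit)
  rep <- run_experiment(coh$stays, ncit, scenario = "single",
                        moments = c("in_icu", "post_icu"), models = "LR",
                        dimension = 8, seed = 7,
                        embed_params = list(epochs = 2))
  expect_equal(nrow(rep$metrics), 2 * 5)
  # exactly one comparison per metric per model for two configurations
  expect_equal(nrow(rep$kruskal), 2)
  expect_setequal(rep$kruskal$metric, c("auroc", "auprc"))
  # average confusion still accounts for the average fold size
  n <- nrow(coh$stays)
  expect_equal(rowSums(rep$confusion[c("tn", "fp", "fn", "tp")]),
               rep(n / 5, 2), ignore_attr = TRUE)
  expect_error(run_experiment(coh$stays, ncit, moments = "mid_icu"),
               "unknown snapshot")
})

test_that("a cohort without planted signal predicts at chance", {
  ncit <- list(NCIT = test_suite$ontologies$NCIT)
  coh <- generate_cohort(cohort_spec(n_patients = 300, readmission_rate = 0.25,
                                     signal_strength = 1, seed = 77), ncit)
  rep <- run_experiment(coh$stays, ncit, scenario = "single",
                        moments = "in_icu", models = "RF", dimension = 16,
                        seed = 5, embed_params = list(epochs = 2))
  expect_gt(mean(rep$metrics$auroc), 0.35)
  expect_lt(mean(rep$metrics$auroc), 0.65)
})
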