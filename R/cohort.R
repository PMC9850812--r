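# Synthetic ICU cohort generator. Emulates the shape of critical-care EHR
# exports (one row per ICU stay, timed events, free-text initial diagnoses,
# unformatted ICD9-like codes, coded labs and drugs, a 17-feature chart-event
# block) with a planted readmission signal carried by designated ontology
# classes, so the full annotation -> knowledge graph -> embedding -> prediction
# pipeline is exercisable without access-controlled data.

.ICU_WARDS <- c("MICU", "SICU", "CSRU", "CCU", "TSICU")
.LOW_WARDS <- c("MED", "SURG", "ORTHO", "NEURO-WARD")
.MINUTES_PER_DAY <- 1440L
.MINUTES_PER_YEAR <- 525600L

#' Specify a synthetic cohort
#'
#' @param n_patients Number of patients (one index ICU stay each).
#' @param readmission_rate Fraction of stays engineered to satisfy one of the
#'   four readmission criteria (exact-prevalence: exactly
#'   `round(rate * n_stays)` stays are positive).
#' @param signal_classes Optional character vector of ontology classes whose
#'   presence raises readmission odds. When `NULL`, one subtree per ontology
#'   (roughly 20% of its classes) is chosen deterministically from the seed.
#' @param signal_strength Odds multiplier (>= 1) applied when a positive stay
#'   draws feature concepts: 1 plants no signal.
#' @param missing_initial_dx_rate Fraction of stays with no initial diagnosis
#'   text (exact count, seeded choice).
#' @param dirty_label_rate Per-term probability that a diagnosis label is
#'   corrupted to an empty or non-alphanumeric string.
#' @param n_chart_features Width of the numeric chart-event block (default 17).
#' @param chart_missing_rate Missing-completely-at-random rate for chart
#'   values.
#' @param seed Integer seed; the whole cohort is a pure function of the spec
#'   and the ontologies.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients, readmission_rate = 0.25,
                        signal_classes = NULL, signal_strength = 4,
                        missing_initial_dx_rate = 0.02,
                        dirty_label_rate = 0.05, n_chart_features = 17,
                        chart_missing_rate = 0.1, seed = 1) {
  assert_that(is_scalar_number(n_patients) && n_patients >= 1,
              "n_patients must be >= 1")
  for (r in c(readmission_rate, missing_initial_dx_rate, dirty_label_rate,
              chart_missing_rate)) {
    assert_that(is_scalar_number(r) && r >= 0 && r <= 1,
                "rates must lie in [0, 1]")
  }
  assert_that(is_scalar_number(signal_strength) && signal_strength >= 1,
              "signal_strength must be >= 1")
  structure(list(n_patients = as.integer(n_patients),
                 readmission_rate = readmission_rate,
                 signal_classes = signal_classes,
                 signal_strength = signal_strength,
                 missing_initial_dx_rate = missing_initial_dx_rate,
                 dirty_label_rate = dirty_label_rate,
                 n_chart_features = as.integer(n_chart_features),
                 chart_missing_rate = chart_missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# map annotated feature types onto ontologies; with a single ontology all
# types draw from (and later annotate against) it
ontology_roles <- function(ontologies) {
  stopifnot(length(ontologies) >= 1)
  acr <- vapply(ontologies, function(o) o$acronym, "")
  if (is.null(names(ontologies)) || any(!nzchar(names(ontologies)))) {
    names(ontologies) <- acr
  }
  if (length(ontologies) == 1L) {
    roles <- stats::setNames(rep(names(ontologies), 5),
                             annotated_feature_types())
  } else {
    pick <- function(pref) if (pref %in% names(ontologies)) pref else names(ontologies)[1]
    roles <- c(initial_dx = pick("NCIT"), labs = pick("LOINC"),
               prescriptions = pick("DRON"), final_dx = pick("ICD9"),
               procedures = pick("ICD9"))
  }
  roles
}

# default signal subtree per ontology: the internal node whose descendant set
# is closest to 20% of the ontology
default_signal_classes <- function(ont) {
  target <- max(2L, round(0.2 * length(ont$classes)))
  internal <- unique(ont$subclass_edges$parent)
  if (length(internal) == 0) return(ont$classes[1])
  sizes <- vapply(internal, function(cl)
    length(class_descendants(ont, cl)), 1L)
  internal[order(abs(sizes - target), internal)][1]
}

# candidate class pools per feature type (ICD9-style ontologies split into
# diagnosis-form and procedure-form identifiers)
class_pool <- function(ont, feature_type) {
  if (feature_type %in% c("final_dx", "procedures") &&
      any(grepl("^\\d{3}\\.", ont$classes))) {
    dx <- grepl("^\\d{3}\\.\\d$", ont$classes)
    pool <- if (feature_type == "final_dx") ont$classes[dx] else ont$classes[!dx]
    if (length(pool) > 0) return(pool)
  }
  ont$classes
}

sample_concepts <- function(n, pool, sig_pool, p_signal) {
  sig_pool <- intersect(sig_pool, pool)
  if (length(sig_pool) == 0 || p_signal <= 0) {
    return(sample(pool, n, replace = TRUE))
  }
  k <- stats::rbinom(1, n, p_signal)
  c(if (k > 0) sample(sig_pool, k, replace = TRUE),
    if (n - k > 0) sample(setdiff(pool, sig_pool), n - k, replace = TRUE))
}

concept_text <- function(ont, cls, synonym_prob = 0.4) {
  vapply(cls, function(cl) {
    syns <- ont$synonyms[[cl]]
    if (length(syns) > 0 && stats::runif(1) < synonym_prob) {
      sample(syns, 1)
    } else {
      unname(ont$labels[[cl]])
    }
  }, "", USE.NAMES = FALSE)
}

corrupt_labels <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) return(x)
  hit <- stats::runif(length(x)) < rate
  x[hit] <- sample(c("", "----", "..", "??"), sum(hit), replace = TRUE)
  x
}

strip_icd9 <- function(code) gsub(".", "", code, fixed = TRUE)

#' Generate a synthetic ICU cohort
#'
#' Produces one index ICU stay per patient with demographics, a minute-
#' resolution timeline, free-text and coded clinical features drawn from the
#' supplied toy ontologies, and a ground-truth 30-day readmission label.
#' Exactly `round(readmission_rate * n)` stays are engineered to satisfy one
#' of the four readmission criteria (ward return, ward death, 30-day ICU
#' return, 30-day death); positive stays draw their feature concepts
#' preferentially from `signal_classes` and their descendants with odds
#' multiplied by `signal_strength`.
#'
#' @param spec A [cohort_spec()].
#' @param ontologies Non-empty named list of [toy_ontology()] objects (a
#'   single general ontology, or the four-ontology suite from
#'   [toy_ontology_suite()]).
#' @param ndc_table Optional NDC-to-drug-ontology lookup table used to stamp
#'   NDC-like codes on prescriptions.
#' @return A list of class `icu_cohort`: `stays` (data frame, one row per
#'   stay, event/term fields as list columns), `labels` (stay_id, label,
#'   criterion), `signal_classes`, `roles`, `spec`.
#' @export
generate_cohort <- function(spec, ontologies, ndc_table = NULL) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  assert_that(length(ontologies) >= 1, "ontologies must be non-empty")
  if (inherits(ontologies, "toy_ontology")) ontologies <- list(ontologies)
  acr <- vapply(ontologies, function(o) o$acronym, "")
  if (is.null(names(ontologies)) || any(!nzchar(names(ontologies)))) {
    names(ontologies) <- acr
  }
  roles <- ontology_roles(ontologies)

  with_local_seed(spec$seed, {
    n <- spec$n_patients

    # signal pools (class + descendants) per ontology
    sig_roots <- spec$signal_classes
    if (is.null(sig_roots)) {
      sig_roots <- unlist(lapply(ontologies, default_signal_classes),
                          use.names = FALSE)
    }
    sig_pools <- lapply(ontologies, function(o)
      class_descendants(o, intersect(sig_roots, o$classes)))
    p_sig <- lapply(names(ontologies), function(nm) {
      q <- length(sig_pools[[nm]]) / length(ontologies[[nm]]$classes)
      odds <- q / max(1 - q, 1e-9)
      c(neg = q, pos = (spec$signal_strength * odds) /
          (1 + spec$signal_strength * odds))
    })
    names(p_sig) <- names(ontologies)

    # outcome engineering: exact prevalence, criterion drawn uniformly
    n_pos <- round(spec$readmission_rate * n)
    pos_idx <- if (n_pos > 0) sample(n, n_pos) else integer(0)
    is_pos <- seq_len(n) %in% pos_idx
    crit <- rep("none", n)
    crit[is_pos] <- sample(c("ward_return", "ward_death", "readmit_30d",
                             "death_30d"), n_pos, replace = TRUE)

    # demographics
    age <- sample(18:90, n, replace = TRUE)
    gender <- sample(c("F", "M"), n, replace = TRUE)
    ethnicity <- sample(c("WHITE", "BLACK", "HISPANIC", "ASIAN", "OTHER"),
                        n, replace = TRUE)
    insurance <- sample(c("Medicare", "Medicaid", "Private", "Government",
                          "Self Pay"), n, replace = TRUE)

    # timeline (integer minutes from epoch); engineered event times use exact
    # day multiples so calendar-day arithmetic is unambiguous
    admit <- sample.int(365L * .MINUTES_PER_DAY, n, replace = TRUE)
    intime <- admit + sample.int(48L * 60L, n, replace = TRUE)
    outtime <- intime + .MINUTES_PER_DAY +
      sample.int(14L * .MINUTES_PER_DAY, n, replace = TRUE)
    discharge <- outtime + sample.int(10L * .MINUTES_PER_DAY, n, replace = TRUE)
    death <- rep(NA_integer_, n)
    next_icu <- rep(NA_integer_, n)
    transfers <- vector("list", n)

    for (i in seq_len(n)) {
      ward <- sample(.LOW_WARDS, 1)
      tr <- NULL
      if (crit[i] == "ward_return") {
        back <- sample(.ICU_WARDS, 1)
        t1 <- outtime[i]
        t2 <- t1 + sample.int(3L * .MINUTES_PER_DAY, 1)
        discharge[i] <- t2 + sample.int(7L * .MINUTES_PER_DAY, 1)
        tr <- data.frame(time = c(t1, t2), destination = c(ward, back),
                         stringsAsFactors = FALSE)
      } else if (crit[i] == "ward_death") {
        t1 <- outtime[i]
        death[i] <- t1 + sample.int(5L * .MINUTES_PER_DAY, 1)
        discharge[i] <- death[i]
        tr <- data.frame(time = t1, destination = ward,
                         stringsAsFactors = FALSE)
      } else if (crit[i] == "readmit_30d") {
        next_icu[i] <- discharge[i] +
          sample(1:30, 1) * .MINUTES_PER_DAY
        tr <- data.frame(time = outtime[i], destination = ward,
                         stringsAsFactors = FALSE)
      } else if (crit[i] == "death_30d") {
        death[i] <- discharge[i] + sample(1:30, 1) * .MINUTES_PER_DAY
        tr <- data.frame(time = outtime[i], destination = ward,
                         stringsAsFactors = FALSE)
      } else {
        # negatives: plain ward stay; some late (> 30 day) returns or deaths
        # that must NOT trigger a positive label
        if (stats::runif(1) < 0.7) {
          tr <- data.frame(time = outtime[i], destination = ward,
                           stringsAsFactors = FALSE)
        }
        u <- stats::runif(1)
        if (u < 0.10) {
          death[i] <- discharge[i] + sample(31:365, 1) * .MINUTES_PER_DAY
        } else if (u < 0.25) {
          next_icu[i] <- discharge[i] + sample(31:200, 1) * .MINUTES_PER_DAY
        }
      }
      transfers[[i]] <- tr %||% data.frame(time = integer(),
                                           destination = character(),
                                           stringsAsFactors = FALSE)
    }

    # clinical concepts per feature type
    n_initial <- pmin(1L + stats::rpois(n, 0.8), 3L)
    miss_idx <- if (spec$missing_initial_dx_rate > 0) {
      sample(n, round(spec$missing_initial_dx_rate * n))
    } else integer(0)
    n_final <- sample(3:8, n, replace = TRUE)
    n_proc <- sample(1:3, n, replace = TRUE)
    n_rx <- sample(2:6, n, replace = TRUE)
    n_lab <- sample(3:8, n, replace = TRUE)

    draw <- function(i, feature_type, count) {
      ont <- ontologies[[roles[[feature_type]]]]
      pool <- class_pool(ont, feature_type)
      p <- p_sig[[roles[[feature_type]]]][[if (is_pos[i]) "pos" else "neg"]]
      cls <- sample_concepts(count, pool, sig_pools[[roles[[feature_type]]]], p)
      list(ont = ont, classes = cls)
    }

    initial_dx_texts <- vector("list", n)
    final_dx_entries <- vector("list", n)
    procedure_entries <- vector("list", n)
    prescription_entries <- vector("list", n)
    lab_entries <- vector("list", n)

    ndc_of <- if (!is.null(ndc_table)) {
      stats::setNames(ndc_table$ndc, ndc_table$class_id)
    } else NULL

    for (i in seq_len(n)) {
      d <- draw(i, "initial_dx", n_initial[i])
      txt <- corrupt_labels(concept_text(d$ont, d$classes),
                            spec$dirty_label_rate)
      initial_dx_texts[[i]] <- if (i %in% miss_idx) character(0) else txt

      d <- draw(i, "final_dx", n_final[i])
      final_dx_entries[[i]] <- data.frame(
        code = strip_icd9(d$classes),
        label = corrupt_labels(concept_text(d$ont, d$classes, 0),
                               spec$dirty_label_rate),
        stringsAsFactors = FALSE)

      d <- draw(i, "procedures", n_proc[i])
      procedure_entries[[i]] <- data.frame(
        code = strip_icd9(d$classes),
        label = concept_text(d$ont, d$classes, 0),
        stringsAsFactors = FALSE)

      d <- draw(i, "prescriptions", n_rx[i])
      prescription_entries[[i]] <- data.frame(
        drug = concept_text(d$ont, d$classes, 0),
        ndc = if (!is.null(ndc_of)) {
          unname(ifelse(d$classes %in% names(ndc_of), ndc_of[d$classes], ""))
        } else rep("", length(d$classes)),
        stringsAsFactors = FALSE)

      d <- draw(i, "labs", n_lab[i])
      lab_entries[[i]] <- data.frame(
        label = concept_text(d$ont, d$classes, 0),
        code = d$classes,
        stringsAsFactors = FALSE)
    }

    # chart events: per-feature Gaussians, MCAR missingness
    mu <- stats::rnorm(spec$n_chart_features, 100, 20)
    sd <- stats::runif(spec$n_chart_features, 5, 15)
    chart <- matrix(stats::rnorm(n * spec$n_chart_features,
                                 rep(mu, each = n), rep(sd, each = n)),
                    nrow = n)
    if (spec$chart_missing_rate > 0) {
      chart[stats::runif(length(chart)) < spec$chart_missing_rate] <- NA
    }
    colnames(chart) <- sprintf("chart_%02d", seq_len(spec$n_chart_features))
    chart_events <- lapply(seq_len(n), function(i) chart[i, ])

    stays <- data.frame(
      patient_id = 10000L + seq_len(n),
      stay_id = 200000L + seq_len(n),
      admission_id = 100000L + seq_len(n),
      age = age, gender = gender, ethnicity = ethnicity,
      insurance = insurance,
      intime = intime, outtime = outtime, discharge_time = discharge,
      death_time = death, next_icu_intime = next_icu,
      stringsAsFactors = FALSE)
    stays$ward_transfer_events <- transfers
    stays$initial_dx_texts <- initial_dx_texts
    stays$final_dx_entries <- final_dx_entries
    stays$procedure_entries <- procedure_entries
    stays$prescription_entries <- prescription_entries
    stays$lab_entries <- lab_entries
    stays$chart_events <- chart_events

    labels <- data.frame(stay_id = stays$stay_id,
                         label = ifelse(is_pos, "positive", "negative"),
                         criterion = crit, stringsAsFactors = FALSE)

    structure(list(stays = stays, labels = labels,
                   signal_classes = unlist(sig_pools, use.names = FALSE),
                   roles = roles, spec = spec),
              class = "icu_cohort")
  })
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat(sprintf("icu_cohort: %d stays (%d readmission-positive), %d ontologies\n",
              nrow(x$stays), sum(x$labels$label == "positive"),
              length(unique(x$roles))))
  invisible(x)
}
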