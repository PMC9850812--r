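# Cleaning, ICD9 reconstruction, cohort filters, 30-day readmission labelling
# and the Pre/In/Post-ICU snapshot split.

#' Reconstruct formatted ICD9 codes
#'
#' EHR exports often drop the period from ICD9 codes, which makes codes from
#' different branches ambiguous. Because procedure and diagnosis codes are
#' stored in separate tables, the period can be reinserted deterministically:
#' after the second character for procedures, after the third for diagnoses.
#' Codes already containing a period are returned unchanged (the operation is
#' idempotent); codes no longer than the split position are returned
#' unchanged and flagged.
#'
#' @param code Character vector of non-empty alphanumeric codes.
#' @param kind `"procedure"` or `"diagnosis"`.
#' @return Character vector of formatted codes with a logical attribute
#'   `short_code` marking entries too short to split.
#' @examples
#' reformat_icd9("0331", "procedure")  # "03.31"
#' reformat_icd9("4019", "diagnosis")  # "401.9"
#' @export
reformat_icd9 <- function(code, kind = c("procedure", "diagnosis")) {
  kind <- match.arg(kind)
  assert_that(is.character(code) && length(code) >= 1 && all(!is.na(code)) &&
                all(nzchar(code)), "codes must be non-empty strings")
  pos <- if (kind == "procedure") 2L else 3L
  has_dot <- grepl(".", code, fixed = TRUE)
  short <- !has_dot & nchar(code) <= pos
  out <- code
  todo <- !has_dot & !short
  out[todo] <- paste0(substr(code[todo], 1, pos),
                      ".", substring(code[todo], pos + 1))
  attr(out, "short_code") <- short
  out
}

valid_label <- function(x) !is.na(x) & grepl("[[:alnum:]]", x)

#' Remove terms with missing or unreadable labels
#'
#' Drops feature entries whose label is empty or contains no alphanumeric
#' character (e.g. a lone dash or period), per feature type, and reports the
#' exclusion counts.
#'
#' @param stays Stays data frame (simulator layout).
#' @return List with `stays` (cleaned) and `report`, a data frame of
#'   `feature_type`, `original`, `removed`, `retained` satisfying
#'   `removed + retained == original`.
#' @export
clean_terms <- function(stays) {
  counts <- stats::setNames(numeric(0), character(0))
  tally <- function(ft, orig, kept) {
    counts[[ft]] <<- if (ft %in% names(counts)) counts[[ft]] else 0
    counts[[paste0(ft, ".rm")]] <<-
      (if (paste0(ft, ".rm") %in% names(counts)) counts[[paste0(ft, ".rm")]] else 0) +
      (orig - kept)
    counts[[ft]] <<- counts[[ft]] + orig
  }
  stays$initial_dx_texts <- lapply(stays$initial_dx_texts, function(x) {
    keep <- valid_label(x)
    tally("initial_dx", length(x), sum(keep))
    x[keep]
  })
  clean_df <- function(col, ft, label_col) {
    lapply(stays[[col]], function(d) {
      keep <- valid_label(d[[label_col]])
      tally(ft, nrow(d), sum(keep))
      d[keep, , drop = FALSE]
    })
  }
  stays$final_dx_entries <- clean_df("final_dx_entries", "final_dx", "label")
  stays$procedure_entries <- clean_df("procedure_entries", "procedures", "label")
  stays$prescription_entries <- clean_df("prescription_entries",
                                         "prescriptions", "drug")
  stays$lab_entries <- clean_df("lab_entries", "labs", "label")
  fts <- c("initial_dx", "labs", "prescriptions", "final_dx", "procedures")
  report <- data.frame(
    feature_type = fts,
    original = vapply(fts, function(f) counts[[f]] %||% 0, 0),
    removed = vapply(fts, function(f) counts[[paste0(f, ".rm")]] %||% 0, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  report$retained <- report$original - report$removed
  list(stays = stays, report = report)
}

#' Keep adult patients only
#'
#' Patients under 18 are removed. The de-identification convention that
#' records ages above 89 as ~300 is normalized to 90 first.
#'
#' @param stays Stays data frame.
#' @return The filtered data frame.
#' @export
filter_adults <- function(stays) {
  assert_that(all(!is.na(stays$age)), "age must be present for every patient")
  assert_that(all(stays$age >= 0), "negative age encountered")
  stays$age[stays$age > 89] <- 90L
  stays[stays$age >= 18, , drop = FALSE]
}

is_icu_ward <- function(dest) dest %in% .ICU_WARDS | grepl("ICU", dest)

day_of <- function(t) t %/% .MINUTES_PER_DAY

#' Assign 30-day readmission labels
#'
#' A stay is positive when one of four criteria holds, checked in order:
#' (1) `ward_return` — transferred from ICU to a low-level ward and later
#' returned to an ICU ward within the same hospital admission;
#' (2) `ward_death` — transferred to a low-level ward and died in hospital
#' (unbounded within the admission by default; bound with
#' `ward_death_window_days`); (3) `readmit_30d` — discharged and admitted to
#' an ICU again within `window_days`; (4) `death_30d` — discharged and died
#' within `window_days`. Windows are closed (day `window_days` inclusive) and
#' computed on calendar-day differences. "Low-level ward" means any transfer
#' destination that is not an ICU ward.
#'
#' Labelling is a pure per-stay function of the stay's timeline; the next ICU
#' admission is taken from `next_icu_intime` or, when absent, from later
#' stays of the same patient in `stays`.
#'
#' @param stays Stays data frame.
#' @param window_days Closed window length in days (default 30).
#' @param ward_death_window_days Optional bound (days after ward transfer)
#'   for criterion 2; `NULL` (default) leaves it unbounded in-admission.
#' @return Data frame `stay_id`, `label` (`"positive"`/`"negative"`),
#'   `criterion` (one of `ward_return`, `ward_death`, `readmit_30d`,
#'   `death_30d`, `none`).
#' @export
label_readmission <- function(stays, window_days = 30,
                              ward_death_window_days = NULL) {
  assert_that(all(stays$outtime > stays$intime),
              "stay with outtime before intime")
  n <- nrow(stays)
  crit <- rep("none", n)
  for (i in seq_len(n)) {
    tr <- stays$ward_transfer_events[[i]]
    death <- stays$death_time[i]
    disch <- stays$discharge_time[i]
    low <- which(!is_icu_ward(tr$destination))
    # (1) ward transfer then ICU return within the same admission
    if (length(low) > 0) {
      first_low <- min(tr$time[low])
      back <- which(is_icu_ward(tr$destination) & tr$time > first_low)
      if (length(back) > 0) { crit[i] <- "ward_return"; next }
    }
    # (2) ward transfer then in-hospital death
    if (length(low) > 0 && !is.na(death) && death <= disch) {
      ok <- TRUE
      if (!is.null(ward_death_window_days)) {
        ok <- day_of(death) - day_of(min(tr$time[low])) <= ward_death_window_days
      }
      if (ok) { crit[i] <- "ward_death"; next }
    }
    # next ICU admission: explicit field, else later stays of the patient
    nxt <- stays$next_icu_intime[i]
    if (is.na(nxt)) {
      later <- stays$intime[stays$patient_id == stays$patient_id[i] &
                              stays$intime > disch]
      if (length(later) > 0) nxt <- min(later)
    }
    # (3) discharged, ICU return within the closed window
    if (!is.na(nxt) && nxt >= disch &&
        day_of(nxt) - day_of(disch) <= window_days) {
      crit[i] <- "readmit_30d"; next
    }
    # (4) discharged, death within the closed window
    if (!is.na(death) && death >= disch &&
        day_of(death) - day_of(disch) <= window_days) {
      crit[i] <- "death_30d"
    }
  }
  data.frame(stay_id = stays$stay_id,
             label = ifelse(crit == "none", "negative", "positive"),
             criterion = crit, stringsAsFactors = FALSE)
}

#' Feature types available at an ICU timeline snapshot
#'
#' @param moment `"pre_icu"`, `"in_icu"` or `"post_icu"`.
#' @return Character vector of feature types; the three sets are strictly
#'   nested.
#' @export
snapshot_features <- function(moment = c("pre_icu", "in_icu", "post_icu")) {
  moment <- match.arg(moment)
  pre <- c("demographics", "initial_dx")
  in_icu <- c(pre, "labs", "prescriptions", "chart_events")
  post <- c(in_icu, "final_dx", "procedures")
  switch(moment, pre_icu = pre, in_icu = in_icu, post_icu = post)
}

#' Split a cohort at an ICU timeline moment
#'
#' Returns the feature types visible at the moment and the stays eligible for
#' it. Procedures, although performed during the stay, are recorded only at
#' discharge and therefore belong to the post-ICU snapshot. Stays with no
#' initial diagnosis text are excluded from the pre-ICU cohort only (they
#' keep other features at later moments).
#'
#' @param stays Stays data frame.
#' @param moment `"pre_icu"`, `"in_icu"` or `"post_icu"`.
#' @return List of class `snapshot_view`: `moment`, `feature_types`,
#'   `stay_ids`.
#' @export
snapshot_split <- function(stays, moment) {
  assert_that(is.character(moment) && length(moment) == 1 &&
                moment %in% c("pre_icu", "in_icu", "post_icu"),
              paste("unknown snapshot moment:", paste(moment, collapse = ",")))
  ids <- stays$stay_id
  if (moment == "pre_icu") {
    has_dx <- vapply(stays$initial_dx_texts, function(x)
      sum(valid_label(x)) > 0, TRUE)
    ids <- ids[has_dx]
  }
  structure(list(moment = moment, feature_types = snapshot_features(moment),
                 stay_ids = ids),
            class = "snapshot_view")
}

#' @export
print.snapshot_view <- function(x, ...) {
  cat(sprintf("snapshot '%s': %d stays, features {%s}\n", x$moment,
              length(x$stay_ids), paste(x$feature_types, collapse = ", ")))
  invisible(x)
}

#' Clean, filter and label a cohort in one step
#'
#' Convenience wrapper chaining [clean_terms()], [filter_adults()] and
#' [label_readmission()], and reformatting the raw diagnosis/procedure codes
#' via [reformat_icd9()].
#'
#' @param stays Stays data frame.
#' @param window_days Readmission window, see [label_readmission()].
#' @return List `stays`, `labels`, `exclusion_report`.
#' @export
prepare_cohort <- function(stays, window_days = 30) {
  cleaned <- clean_terms(stays)
  stays <- filter_adults(cleaned$stays)
  stays$final_dx_entries <- lapply(stays$final_dx_entries, function(d) {
    if (nrow(d) > 0) d$code <- as.character(reformat_icd9(d$code, "diagnosis"))
    d
  })
  stays$procedure_entries <- lapply(stays$procedure_entries, function(d) {
    if (nrow(d) > 0) d$code <- as.character(reformat_icd9(d$code, "procedure"))
    d
  })
  labels <- label_readmission(stays, window_days)
  list(stays = stays, labels = labels, exclusion_report = cleaned$report)
}
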