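# CSV exchange mirroring the table layout of critical-care EHR exports
# (PATIENTS, ADMISSIONS, ICUSTAYS, TRANSFERS, DIAGNOSES_ICD, PROCEDURES_ICD,
# PRESCRIPTIONS, LABEVENTS and a CHARTEVENTS subset). Timestamps are integer
# minutes from a common epoch. ICUSTAYS carries one extra column,
# NEXT_ICU_INTIME, our per-stay abstraction of the patient's next ICU
# admission needed to evaluate the 30-day return criterion on index stays.

.MIMIC_TABLES <- c("PATIENTS", "ADMISSIONS", "ICUSTAYS", "TRANSFERS",
                   "DIAGNOSES_ICD", "PROCEDURES_ICD", "PRESCRIPTIONS",
                   "LABEVENTS", "CHARTEVENTS")

#' Write a cohort as MIMIC-style CSV tables
#'
#' Initial diagnosis texts are joined with `";"` in ADMISSIONS.DIAGNOSIS;
#' dates of birth are derived from age at ICU admission. A stay whose only
#' initial diagnosis is the empty string is indistinguishable from a stay
#' with none after a round trip (both serialize to an empty DIAGNOSIS field);
#' the cleaning step removes either.
#'
#' @param cohort An `icu_cohort` or its `stays` data frame.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mimic_csvs <- function(cohort, dir) {
  stays <- if (inherits(cohort, "icu_cohort")) cohort$stays else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
  }
  w(data.frame(SUBJECT_ID = stays$patient_id, GENDER = stays$gender,
               DOB = stays$intime - stays$age * .MINUTES_PER_YEAR),
    "PATIENTS")
  w(data.frame(SUBJECT_ID = stays$patient_id, HADM_ID = stays$admission_id,
               ADMITTIME = stays$intime, DISCHTIME = stays$discharge_time,
               DEATHTIME = stays$death_time, ETHNICITY = stays$ethnicity,
               INSURANCE = stays$insurance,
               DIAGNOSIS = vapply(stays$initial_dx_texts, paste,
                                  "", collapse = ";")),
    "ADMISSIONS")
  w(data.frame(SUBJECT_ID = stays$patient_id, HADM_ID = stays$admission_id,
               ICUSTAY_ID = stays$stay_id, INTIME = stays$intime,
               OUTTIME = stays$outtime,
               NEXT_ICU_INTIME = stays$next_icu_intime),
    "ICUSTAYS")
  per_stay <- function(col, f) {
    do.call(rbind, lapply(seq_len(nrow(stays)), function(i) {
      x <- stays[[col]][[i]]
      if (NROW(x) == 0) return(NULL)
      cbind(data.frame(SUBJECT_ID = stays$patient_id[i],
                       HADM_ID = stays$admission_id[i],
                       ICUSTAY_ID = stays$stay_id[i]), f(x))
    }))
  }
  empty_or <- function(df, proto) if (is.null(df)) proto else df
  w(empty_or(per_stay("ward_transfer_events", function(x)
      data.frame(CURR_CAREUNIT = x$destination, INTIME = x$time)),
    data.frame(SUBJECT_ID = integer(), HADM_ID = integer(),
               ICUSTAY_ID = integer(), CURR_CAREUNIT = character(),
               INTIME = integer())), "TRANSFERS")
  w(empty_or(per_stay("final_dx_entries", function(x)
      data.frame(ICD9_CODE = x$code, LABEL = x$label)),
    data.frame(SUBJECT_ID = integer(), HADM_ID = integer(),
               ICUSTAY_ID = integer(), ICD9_CODE = character(),
               LABEL = character())), "DIAGNOSES_ICD")
  w(empty_or(per_stay("procedure_entries", function(x)
      data.frame(ICD9_CODE = x$code, LABEL = x$label)),
    data.frame(SUBJECT_ID = integer(), HADM_ID = integer(),
               ICUSTAY_ID = integer(), ICD9_CODE = character(),
               LABEL = character())), "PROCEDURES_ICD")
  w(empty_or(per_stay("prescription_entries", function(x)
      data.frame(DRUG = x$drug, NDC = x$ndc)),
    data.frame(SUBJECT_ID = integer(), HADM_ID = integer(),
               ICUSTAY_ID = integer(), DRUG = character(),
               NDC = character())), "PRESCRIPTIONS")
  w(empty_or(per_stay("lab_entries", function(x)
      data.frame(LOINC_CODE = x$code, LABEL = x$label)),
    data.frame(SUBJECT_ID = integer(), HADM_ID = integer(),
               ICUSTAY_ID = integer(), LOINC_CODE = character(),
               LABEL = character())), "LABEVENTS")
  chart <- do.call(rbind, lapply(seq_len(nrow(stays)), function(i) {
    v <- stays$chart_events[[i]]
    data.frame(ICUSTAY_ID = stays$stay_id[i], ITEMID = seq_along(v),
               VALUENUM = unname(v))
  }))
  w(chart, "CHARTEVENTS")
  invisible(dir)
}

#' Read a cohort from MIMIC-style CSV tables
#'
#' Inverse of [write_mimic_csvs()]: rebuilds the per-stay record table
#' (ages recomputed from DOB and ICU admission time).
#'
#' @param dir Directory holding the CSV tables.
#' @return A stays data frame with the same layout the simulator produces.
#' @export
read_mimic_csvs <- function(dir) {
  r <- function(name, classes = NA) {
    utils::read.csv(file.path(dir, paste0(name, ".csv")), na.strings = "",
                    stringsAsFactors = FALSE, colClasses = classes)
  }
  pat <- r("PATIENTS")
  adm <- r("ADMISSIONS")
  icu <- r("ICUSTAYS")
  tra <- r("TRANSFERS")
  dx <- r("DIAGNOSES_ICD", c(NA, NA, NA, "character", "character"))
  px <- r("PROCEDURES_ICD", c(NA, NA, NA, "character", "character"))
  rx <- r("PRESCRIPTIONS")
  lab <- r("LABEVENTS", c(NA, NA, NA, "character", "character"))
  chart <- r("CHARTEVENTS")

  icu <- icu[order(icu$ICUSTAY_ID), ]
  m <- merge(icu, adm, by = c("SUBJECT_ID", "HADM_ID"), sort = FALSE)
  m <- merge(m, pat, by = "SUBJECT_ID", sort = FALSE)
  m <- m[order(m$ICUSTAY_ID), ]
  n <- nrow(m)

  pick <- function(tab, id, build, proto) {
    idx <- split(seq_len(nrow(tab)), tab$ICUSTAY_ID)
    lapply(m$ICUSTAY_ID, function(sid) {
      rows <- idx[[as.character(sid)]]
      if (is.null(rows)) proto else build(tab[rows, , drop = FALSE])
    })
  }
  stays <- data.frame(
    patient_id = m$SUBJECT_ID, stay_id = m$ICUSTAY_ID,
    admission_id = m$HADM_ID,
    age = as.integer(round((m$INTIME - m$DOB) / .MINUTES_PER_YEAR)),
    gender = m$GENDER, ethnicity = m$ETHNICITY, insurance = m$INSURANCE,
    intime = m$INTIME, outtime = m$OUTTIME, discharge_time = m$DISCHTIME,
    death_time = m$DEATHTIME, next_icu_intime = m$NEXT_ICU_INTIME,
    stringsAsFactors = FALSE)
  stays$ward_transfer_events <- pick(tra, "ICUSTAY_ID", function(d)
    data.frame(time = d$INTIME, destination = d$CURR_CAREUNIT,
               stringsAsFactors = FALSE),
    data.frame(time = integer(), destination = character(),
               stringsAsFactors = FALSE))
  dtxt <- ifelse(is.na(m$DIAGNOSIS), "", m$DIAGNOSIS)
  stays$initial_dx_texts <- lapply(dtxt, function(s)
    if (!nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]])
  stays$final_dx_entries <- pick(dx, "ICUSTAY_ID", function(d)
    data.frame(code = d$ICD9_CODE, label = ifelse(is.na(d$LABEL), "", d$LABEL),
               stringsAsFactors = FALSE),
    data.frame(code = character(), label = character(),
               stringsAsFactors = FALSE))
  stays$procedure_entries <- pick(px, "ICUSTAY_ID", function(d)
    data.frame(code = d$ICD9_CODE, label = ifelse(is.na(d$LABEL), "", d$LABEL),
               stringsAsFactors = FALSE),
    data.frame(code = character(), label = character(),
               stringsAsFactors = FALSE))
  stays$prescription_entries <- pick(rx, "ICUSTAY_ID", function(d)
    data.frame(drug = d$DRUG, ndc = ifelse(is.na(d$NDC), "", d$NDC),
               stringsAsFactors = FALSE),
    data.frame(drug = character(), ndc = character(), stringsAsFactors = FALSE))
  stays$lab_entries <- pick(lab, "ICUSTAY_ID", function(d)
    data.frame(label = d$LABEL, code = d$LOINC_CODE, stringsAsFactors = FALSE),
    data.frame(label = character(), code = character(),
               stringsAsFactors = FALSE))
  stays$chart_events <- pick(chart, "ICUSTAY_ID", function(d) {
    v <- d$VALUENUM[order(d$ITEMID)]
    names(v) <- sprintf("chart_%02d", sort(d$ITEMID))
    v
  }, numeric(0))
  rownames(stays) <- NULL
  stays
}
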