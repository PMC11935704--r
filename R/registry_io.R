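#' Read a procedure-level registry extract
#'
#' One row per cardiac procedure. Raw code cells (semicolon-joined) are
#' translated to concepts via the dictionary; codes the dictionary does not
#' know are preserved in a side tally (attribute `untranslated`) and the
#' record is kept. Rows with unparseable or negative ages are dropped and
#' logged in the `parse_errors` attribute.
#'
#' @param path CSV file with columns patient_id, age_days, procedure_codes,
#'   diagnosis_codes, modality, discharge_age_days, center_id, residency,
#'   born_in_window.
#' @param dictionary a [concept_dictionary()].
#' @return A data.frame of class `chd_procedures` with concept columns
#'   `procedure_concepts` / `diagnosis_concepts` added and attributes
#'   `untranslated` (named counts), `parse_errors` (data.frame) and
#'   `n_dropped`.
#' @export
read_procedure_table <- function(path, dictionary) {
  if (!file.exists(path)) stopf("procedure table not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("patient_id", "age_days", "procedure_codes", "diagnosis_codes",
                "modality", "discharge_age_days", "center_id", "residency",
                "born_in_window")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("procedure table %s: missing mandatory column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  as_procedure_records(df, dictionary)
}

# Shared by read_procedure_table() and the in-memory simulate path.
as_procedure_records <- function(df, dictionary) {
  n0 <- nrow(df)
  df$row <- seq_len(n0)

  errors <- data.frame(row = integer(0), reason = character(0))
  note_error <- function(rows, reason) {
    if (length(rows)) {
      errors <<- rbind(errors, data.frame(row = rows, reason = reason))
    }
  }

  age <- suppressWarnings(as.integer(df$age_days))
  bad_age <- which(is.na(age) | age < 0)
  note_error(df$row[bad_age], "unparseable or negative age_days")

  bad_mod <- which(!(df$modality %in% MODALITIES))
  note_error(df$row[bad_mod], "unknown modality")

  bad_id <- which(is.na(df$patient_id) | !nzchar(df$patient_id))
  note_error(df$row[bad_id], "missing patient_id")

  drop <- sort(unique(c(bad_age, bad_mod, bad_id)))
  keep <- setdiff(seq_len(n0), drop)
  df <- df[keep, , drop = FALSE]
  age <- age[keep]

  discharge <- suppressWarnings(as.integer(df$discharge_age_days))
  # discharge before the procedure violates the record invariant; keep the row
  # but blank the discharge and remember it for the data-error exclusion.
  bad_discharge <- !is.na(discharge) & discharge < age
  discharge[bad_discharge] <- NA_integer_

  proc <- translate_code_column(df$procedure_codes, dictionary)
  diag <- translate_code_column(df$diagnosis_codes, dictionary)
  untranslated <- c(proc$untranslated, diag$untranslated)
  if (length(untranslated)) {
    untranslated <- tapply(as.integer(untranslated),
                           names(untranslated), sum)
  } else {
    untranslated <- integer(0)
  }

  out <- data.frame(
    patient_id = df$patient_id,
    age_days = age,
    procedure_codes = ifelse(is.na(df$procedure_codes), "", df$procedure_codes),
    diagnosis_codes = ifelse(is.na(df$diagnosis_codes), "", df$diagnosis_codes),
    procedure_concepts = proc$concepts,
    diagnosis_concepts = diag$concepts,
    modality = df$modality,
    discharge_age_days = discharge,
    center_id = ifelse(is.na(df$center_id), "", df$center_id),
    residency = ifelse(is.na(df$residency), "england_wales", df$residency),
    born_in_window = toupper(df$born_in_window) %in% c("TRUE", "T", "1"),
    discharge_error = bad_discharge,
    row = df$row,
    stringsAsFactors = FALSE)

  structure(out,
            class = c("chd_procedures", "data.frame"),
            untranslated = untranslated,
            parse_errors = errors,
            n_dropped = length(drop))
}

#' Write a procedure table in the registry CSV dialect
#' @param records a `chd_procedures` data.frame (or the raw-code columns).
#' @param path output CSV path.
#' @export
write_procedure_table <- function(records, path) {
  cols <- c("patient_id", "age_days", "procedure_codes", "diagnosis_codes",
            "modality", "discharge_age_days", "center_id", "residency",
            "born_in_window")
  utils::write.csv(as.data.frame(records)[, cols, drop = FALSE],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read the life-status table
#'
#' @param path CSV with columns patient_id, nchda_death_age_days,
#'   ons_death_age_days, ons_alive_confirm_age_days.
#' @return data.frame with one row per patient.
#' @export
read_life_status <- function(path) {
  if (!file.exists(path)) stopf("life-status table not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("patient_id", "nchda_death_age_days", "ons_death_age_days",
                "ons_alive_confirm_age_days")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("life-status table %s: missing mandatory column(s): %s",
          path, paste(missing, collapse = ", "))
  }
  for (col in required[-1]) df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  check_life_conflicts(df)
}

check_life_conflicts <- function(df) {
  if (anyDuplicated(df$patient_id)) {
    dup_ids <- unique(df$patient_id[duplicated(df$patient_id)])
    conflicting <- vapply(dup_ids, function(id) {
      sub <- df[df$patient_id == id, -1, drop = FALSE]
      nrow(unique(sub)) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stopf("conflicting life-status rows for patient(s): %s",
            paste(dup_ids[conflicting], collapse = ", "))
    }
    df <- df[!duplicated(df$patient_id), , drop = FALSE]
  }
  df
}

#' @export
write_life_status <- function(life, path) {
  utils::write.csv(as.data.frame(life), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Link procedure records and life status into per-patient histories
#'
#' Records are grouped by pseudonymous patient id and sorted by age in days;
#' ties in age keep input row order (stable sort). Patients absent from the
#' life table get an all-absent life status.
#'
#' @param records a `chd_procedures` data.frame.
#' @param life a life-status data.frame (may be missing rows for some ids).
#' @return An object of class `chd_cohort`: list with elements `procedures`
#'   (records sorted by patient, age, input order), `life` (one row per
#'   patient) and `patients` (ids in first-appearance order).
#' @export
link_patients <- function(records, life = NULL) {
  rec <- as.data.frame(records)
  patients <- unique(rec$patient_id)
  ord <- order(match(rec$patient_id, patients), rec$age_days, rec$row,
               method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL

  empty_life <- data.frame(patient_id = patients,
                           nchda_death_age_days = NA_integer_,
                           ons_death_age_days = NA_integer_,
                           ons_alive_confirm_age_days = NA_integer_,
                           stringsAsFactors = FALSE)
  if (!is.null(life) && nrow(life)) {
    life <- check_life_conflicts(as.data.frame(life))
    m <- match(patients, life$patient_id)
    for (col in c("nchda_death_age_days", "ons_death_age_days",
                  "ons_alive_confirm_age_days")) {
      empty_life[[col]] <- life[[col]][m]
    }
  }

  structure(list(procedures = rec, life = empty_life, patients = patients),
            class = "chd_cohort")
}

#' Extract one patient's history from a cohort
#' @param cohort a `chd_cohort`.
#' @param patient_id patient identifier.
#' @return list with `patient_id`, `records` (sorted data.frame) and
#'   `life_status` (one-row data.frame).
#' @export
patient_history <- function(cohort, patient_id) {
  recs <- cohort$procedures[cohort$procedures$patient_id == patient_id, ,
                            drop = FALSE]
  if (!nrow(recs)) stopf("no records for patient %s", patient_id)
  life <- cohort$life[cohort$life$patient_id == patient_id, , drop = FALSE]
  if (!nrow(life)) {
    life <- data.frame(patient_id = patient_id,
                       nchda_death_age_days = NA_integer_,
                       ons_death_age_days = NA_integer_,
                       ons_alive_confirm_age_days = NA_integer_)
  }
  list(patient_id = patient_id, records = recs, life_status = life)
}

#' @export
print.chd_cohort <- function(x, ...) {
  cat("<chd_cohort>", length(x$patients), "patients,",
      nrow(x$procedures), "procedure records\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `chd_cohort`.
#' @export
n_patients <- function(cohort) length(cohort$patients)
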