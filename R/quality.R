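# Data-quality flagging: patients whose procedure sequences are implausible
# for their diagnosis (suspected missing or miscoded data). Flagged patients
# are excluded from reintervention metrics by default but retained for
# survival metrics.

#' Flag implausible procedure sequences for a whole cohort
#'
#' Evaluates the declarative quality rules of the ruleset against the
#' pathway assignments:
#' * q1 - stage 2 filled but stage 1 empty (diagnoses with a possible
#'   single-ventricle pathway);
#' * q2 - stage 3 filled but stage 2 empty;
#' * q3 - exclusively biventricular diagnosis with a stage 2/3 slot filled;
#' * q4 - indeterminate pathway with both repair and stage 2/3 filled;
#' * q5 - first procedure implausibly late for the diagnosis.
#'
#' @param assignments vectorized assignments table from [assign_pathways()].
#' @param first_proc_age named or aligned integer vector of each patient's
#'   first procedure age in days (used by q5); optional.
#' @param ruleset a `chd_ruleset`.
#' @return data.frame with patient_id, flagged, rules_fired (comma-joined).
#' @export
flag_patients <- function(assignments, first_proc_age = NULL,
                          ruleset = load_ruleset()) {
  qr <- ruleset$quality_rules
  n <- nrow(assignments)
  a <- assignments
  fired <- matrix(FALSE, nrow = n, ncol = length(KNOWN_QUALITY_RULES),
                  dimnames = list(NULL, KNOWN_QUALITY_RULES))

  if ("q1" %in% names(qr)) {
    sv_dx <- unlist(qr$q1$single_ventricle_diagnoses) %||% character(0)
    fired[, "q1"] <- a$diagnosis %in% sv_dx &
      !is.na(a$stage2_age) & is.na(a$stage1_age)
  }
  if ("q2" %in% names(qr)) {
    fired[, "q2"] <- !is.na(a$stage3_age) & is.na(a$stage2_age)
  }
  if ("q3" %in% names(qr)) {
    bv_dx <- unlist(qr$q3$biventricular_only) %||% character(0)
    fired[, "q3"] <- a$diagnosis %in% bv_dx &
      (!is.na(a$stage2_age) | !is.na(a$stage3_age))
  }
  if ("q4" %in% names(qr)) {
    fired[, "q4"] <- a$pathway_type == "indeterminate" &
      !is.na(a$repair_age) & (!is.na(a$stage2_age) | !is.na(a$stage3_age))
  }
  if ("q5" %in% names(qr) && !is.null(first_proc_age)) {
    bounds <- unlist(qr$q5$max_first_age_days) %||% numeric(0)
    b <- bounds[a$diagnosis]
    fired[, "q5"] <- !is.na(b) & !is.na(first_proc_age) & first_proc_age > b
  }

  rules_fired <- apply(fired, 1L, function(r) {
    paste(KNOWN_QUALITY_RULES[r], collapse = ",")
  })
  data.frame(patient_id = a$patient_id,
             flagged = nzchar(rules_fired),
             rules_fired = rules_fired,
             stringsAsFactors = FALSE)
}

#' Flag one patient
#'
#' @param history a patient history.
#' @param diagnosis sentinel diagnosis.
#' @param assignment result of [assign_pathway()].
#' @param ruleset a `chd_ruleset`.
#' @return list with `patient_id`, `flagged`, `rules_fired`.
#' @export
flag_patient <- function(history, diagnosis, assignment,
                         ruleset = load_ruleset()) {
  a <- data.frame(patient_id = history$patient_id,
                  diagnosis = diagnosis,
                  stage1_age = assignment$slots[["stage1"]],
                  stage2_age = assignment$slots[["stage2"]],
                  stage3_age = assignment$slots[["stage3"]],
                  repair_age = assignment$slots[["repair"]],
                  pathway_type = assignment$pathway_type,
                  stringsAsFactors = FALSE)
  out <- flag_patients(a, first_proc_age = min(history$records$age_days),
                       ruleset = ruleset)
  list(patient_id = out$patient_id, flagged = out$flagged,
       rules_fired = if (nzchar(out$rules_fired))
         strsplit(out$rules_fired, ",")[[1]] else character(0))
}
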