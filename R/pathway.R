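# Treatment-pathway engine: label each procedure with its pathway role for
# the patient's diagnosis, fill each pathway slot at most once (the
# one-occurrence rule), adjudicate everything beyond the expected pathway as
# reintervention, and determine the pathway type.
#
# Adjudication rules:
#  * Scanning records in age order (ties keep input file order), the first
#    record bearing each role fills that slot.
#  * Every later role-bearing record is a reintervention (a reoperation).
#  * A staged record arriving after a later stage's slot is already filled is
#    adjudicated as reintervention, preserving stage1 <= stage2 <= stage3.
#  * 'other'-role records after the first pathway (stage/repair) procedure
#    are reinterventions; before it, only therapeutic ones are (modality
#    other than electrophysiology) - the prepathway window closes at the
#    first slot procedure.
#  * Prepathway records are never reinterventions; transplant records set the
#    transplant age and are competing events, never reinterventions.

ROLE_PRIORITY <- c(transplant = 1, stage1 = 2, stage2 = 3, stage3 = 4,
                   repair = 5, prepathway = 6, other = 7)

#' Pathway role of a single procedure record
#'
#' The role is looked up from the (diagnosis, procedure concepts) pair;
#' concepts with no role for this diagnosis map to `other`. When a record
#' carries concepts with several distinct roles the most pathway-defining one
#' wins (transplant, then stage 1 < 2 < 3, repair, prepathway).
#'
#' @param record one procedure record (one-row data.frame or list with a
#'   `procedure_concepts` field, semicolon-joined or vector).
#' @param diagnosis sentinel diagnosis.
#' @param dictionary a [concept_dictionary()].
#' @return role string.
#' @export
classify_procedure_role <- function(record, diagnosis, dictionary) {
  stopifnot(diagnosis != "none")
  concepts <- record$procedure_concepts
  if (length(concepts) == 1L && is.character(concepts)) {
    concepts <- split_codes(concepts)
  }
  if (!length(concepts)) return("other")
  roles <- concept_role(concepts, diagnosis, dictionary)
  roles[which.min(ROLE_PRIORITY[roles])]
}

# Core vectorized engine. `rec` must be sorted by (patient, age, input row)
# and grouped contiguously by patient in the order of `patients`.
pathway_engine <- function(rec, patients, diagnosis, dictionary, ruleset) {
  n <- length(patients)
  m <- nrow(rec)
  empty_assign <- data.frame(
    patient_id = character(0), diagnosis = character(0),
    prepathway_age = integer(0), stage1_age = integer(0),
    stage2_age = integer(0), stage3_age = integer(0),
    repair_age = integer(0), transplant_age_days = integer(0),
    pathway_type = character(0), n_reint = integer(0),
    stringsAsFactors = FALSE)
  empty_reint <- data.frame(patient_id = character(0), record_row = integer(0),
                            age_days = integer(0), modality = character(0),
                            category = character(0), stringsAsFactors = FALSE)
  if (!m || !n) return(list(assignments = empty_assign,
                            reinterventions = empty_reint))

  pid_i <- match(rec$patient_id, patients)
  if (is.unsorted(pid_i)) stopf("pathway engine requires patient-grouped records")
  pos <- sequence(tabulate(pid_i, nbins = n))
  dx_rec <- diagnosis[pid_i]

  # Per-record role, by diagnosis.
  role <- rep("other", m)
  concepts <- strsplit(rec$procedure_concepts, ";", fixed = TRUE)
  lens <- lengths(concepts)
  flat <- unlist(concepts, use.names = FALSE)
  rown <- rep.int(seq_len(m), lens)
  keep <- nzchar(flat)
  flat <- flat[keep]; rown <- rown[keep]
  for (dx in setdiff(unique(dx_rec), "none")) {
    sel <- which(dx_rec[rown] == dx)
    if (!length(sel)) next
    r <- concept_role(flat[sel], dx, dictionary)
    pr <- ROLE_PRIORITY[r]
    best <- tapply(pr, rown[sel], min)
    role[as.integer(names(best))] <-
      names(ROLE_PRIORITY)[match(unname(best), ROLE_PRIORITY)]
  }
  role[dx_rec == "none"] <- "other"

  # First occurrence of each role per patient -> candidate slot positions.
  pos_of <- function(r) {
    out <- rep(Inf, n)
    idx <- which(role == r & !duplicated(paste0(pid_i, "\r", role)))
    out[pid_i[idx]] <- pos[idx]
    out
  }
  p_pre <- pos_of("prepathway")
  p_s1 <- pos_of("stage1"); p_s2 <- pos_of("stage2"); p_s3 <- pos_of("stage3")
  p_rep <- pos_of("repair"); p_tx <- pos_of("transplant")

  # Enforce stage monotonicity: a stage slot is valid only if no later-stage
  # slot was filled earlier in the scan.
  v_s3 <- p_s3
  v_s2 <- ifelse(p_s2 < v_s3, p_s2, Inf)
  v_s1 <- ifelse(p_s1 < pmin(v_s2, v_s3), p_s1, Inf)

  first_pathway <- pmin(v_s1, v_s2, v_s3, p_rep)

  # Which records are the chosen slot records?
  key <- pid_i * (max(pos) + 1) + pos
  slot_key <- function(p) ifelse(is.finite(p), seq_len(n) * (max(pos) + 1) + p, NA)
  is_slot <- key %in% c(slot_key(v_s1), slot_key(v_s2), slot_key(v_s3),
                        slot_key(p_rep), slot_key(p_pre), slot_key(p_tx))
  is_slot[is.na(is_slot)] <- FALSE

  reint <- (role %in% c("stage1", "stage2", "stage3", "repair") & !is_slot) |
    (role == "other" &
       (pos > first_pathway[pid_i] |
          (pos < first_pathway[pid_i] & rec$modality != "electrophysiology")))
  reint[dx_rec == "none"] <- FALSE

  age_lookup <- function(p) {
    out <- rep(NA_integer_, n)
    hit <- match(slot_key(p), key)
    ok <- !is.na(hit)
    out[ok] <- rec$age_days[hit[ok]]
    out
  }
  pre_age <- age_lookup(p_pre)
  s1_age <- age_lookup(v_s1)
  s2_age <- age_lookup(v_s2)
  s3_age <- age_lookup(v_s3)
  rep_age <- age_lookup(p_rep)
  tx_age <- age_lookup(p_tx)

  staged <- !is.na(s2_age) | !is.na(s3_age)
  repaired <- !is.na(rep_age)
  pathway_type <- ifelse(staged & !repaired, "single_ventricle",
                         ifelse(repaired & !staged, "biventricular",
                                "indeterminate"))
  pathway_type[diagnosis == "none"] <- "indeterminate"

  surgical_modalities <- ruleset$modality_groups$surgical
  reints <- data.frame(
    patient_id = rec$patient_id[reint],
    record_row = which(reint),
    age_days = rec$age_days[reint],
    modality = rec$modality[reint],
    category = ifelse(rec$modality[reint] %in% surgical_modalities,
                      "surgical", "catheter"),
    stringsAsFactors = FALSE)

  n_reint <- integer(n)
  tab <- table(factor(rec$patient_id[reint], levels = patients))
  n_reint <- as.integer(tab)

  assignments <- data.frame(
    patient_id = patients, diagnosis = diagnosis,
    prepathway_age = pre_age, stage1_age = s1_age, stage2_age = s2_age,
    stage3_age = s3_age, repair_age = rep_age, transplant_age_days = tx_age,
    pathway_type = pathway_type, n_reint = n_reint,
    stringsAsFactors = FALSE)
  list(assignments = assignments, reinterventions = reints)
}

#' Assign expected-pathway slots and reinterventions for a whole cohort
#'
#' @param cohort a `chd_cohort`.
#' @param diagnoses phenotyping table from [assign_diagnoses()].
#' @param dictionary a [concept_dictionary()].
#' @param ruleset a `chd_ruleset`.
#' @return list with `assignments` (one row per patient: slot ages, pathway
#'   type, transplant age, reintervention count) and `reinterventions` (one
#'   row per adjudicated reintervention, with modality category).
#' @export
assign_pathways <- function(cohort, diagnoses,
                            dictionary = default_concept_dictionary(),
                            ruleset = load_ruleset()) {
  dxv <- diagnoses$diagnosis[match(cohort$patients, diagnoses$patient_id)]
  pathway_engine(cohort$procedures, cohort$patients, dxv, dictionary, ruleset)
}

#' Assign the expected pathway for one patient
#'
#' @param history a patient history (records sorted by age).
#' @param diagnosis sentinel diagnosis.
#' @param dictionary a [concept_dictionary()].
#' @param ruleset a `chd_ruleset`.
#' @return list with `slots` (named ages, NA when empty), `reinterventions`
#'   data.frame, `pathway_type` and `transplant_age_days`.
#' @export
assign_pathway <- function(history, diagnosis,
                           dictionary = default_concept_dictionary(),
                           ruleset = load_ruleset()) {
  out <- pathway_engine(history$records, history$patient_id, diagnosis,
                        dictionary, ruleset)
  a <- out$assignments
  list(slots = c(prepathway = a$prepathway_age, stage1 = a$stage1_age,
                 stage2 = a$stage2_age, stage3 = a$stage3_age,
                 repair = a$repair_age),
       reinterventions = out$reinterventions,
       pathway_type = a$pathway_type,
       transplant_age_days = a$transplant_age_days)
}

#' Determine the pathway type from a slot assignment
#'
#' Single-ventricle iff a stage-2 or stage-3 slot is filled and no repair;
#' biventricular iff a repair is filled and no stage-2/3; indeterminate when
#' both or neither (flagged downstream for quality review).
#'
#' @param assignment result of [assign_pathway()] (or a row of the
#'   vectorized assignments table).
#' @return one of `"single_ventricle"`, `"biventricular"`, `"indeterminate"`.
#' @export
determine_pathway_type <- function(assignment) {
  slots <- assignment$slots %||% c(stage2 = assignment$stage2_age,
                                   stage3 = assignment$stage3_age,
                                   repair = assignment$repair_age)
  staged <- !is.na(slots[["stage2"]]) || !is.na(slots[["stage3"]])
  repaired <- !is.na(slots[["repair"]])
  if (staged && !repaired) "single_ventricle"
  else if (repaired && !staged) "biventricular"
  else "indeterminate"
}

#' Pathway completion summary
#'
#' For each diagnosis group and pathway slot, the number and percentage (one
#' decimal) of patients with the slot filled. Percentages are absent (NA)
#' for empty groups.
#'
#' @param assignments vectorized assignments table (one row per patient with
#'   `diagnosis` and the slot age columns).
#' @param by grouping column, default `"diagnosis"`.
#' @return data.frame with columns group, slot, n_group, n_filled, pct.
#' @export
pathway_completion_summary <- function(assignments, by = "diagnosis") {
  slot_cols <- c(prepathway = "prepathway_age", stage1 = "stage1_age",
                 stage2 = "stage2_age", stage3 = "stage3_age",
                 repair = "repair_age")
  groups <- unique(assignments[[by]])
  out <- do.call(rbind, lapply(groups, function(gr) {
    sub <- assignments[assignments[[by]] == gr, , drop = FALSE]
    data.frame(group = gr, slot = names(slot_cols),
               n_group = nrow(sub),
               n_filled = vapply(slot_cols,
                                 function(cl) sum(!is.na(sub[[cl]])),
                                 integer(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out$pct <- pct1(out$n_filled, out$n_group)
  names(out)[1] <- by
  out
}
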