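# Sentinel diagnosis and subgroup assignment from pooled diagnosis concepts,
# complexity flags, and cohort inclusion/exclusion rules.
#
# Assignment is a pure function of the pooled concept multiset: diagnosis
# concepts are pooled across all of a patient's records (later procedures
# often carry fuller coding), so record order and duplication cannot change
# the result. When markers of several sentinel diagnoses are present the
# highest-precedence (most clinically complex) diagnosis wins.

pooled_concepts <- function(records) {
  unique(unlist(lapply(c(records$diagnosis_concepts,
                         records$procedure_concepts), split_codes)))
}

#' Assign the sentinel diagnosis for one patient
#'
#' @param history a patient history (see [patient_history()]).
#' @param dictionary a [concept_dictionary()].
#' @param precedence diagnosis precedence (decreasing complexity); defaults
#'   to the bundled ruleset order.
#' @return list with `diagnosis`, `subgroup`, and `assignment_trace` (ordered
#'   record of candidates and the winner).
#' @export
assign_sentinel_diagnosis <- function(history, dictionary,
                                      precedence = load_ruleset()$precedence) {
  stopifnot(nrow(history$records) >= 1)
  pool <- pooled_concepts(history$records)
  if (!length(pool)) {
    return(list(diagnosis = "none", subgroup = NA_character_,
                assignment_trace = "no cardiac codes"))
  }
  markers <- dictionary$diagnosis_markers[intersect(pool,
                                                    names(dictionary$diagnosis_markers))]
  candidates <- intersect(precedence, unname(markers))
  trace <- c(sprintf("pooled %d concepts", length(pool)),
             sprintf("candidates: %s",
                     if (length(candidates)) paste(candidates, collapse = ", ")
                     else "none"))
  if (!length(candidates)) {
    return(list(diagnosis = "none", subgroup = NA_character_,
                assignment_trace = c(trace, "not a sentinel diagnosis")))
  }
  winner <- candidates[1]
  trace <- c(trace, sprintf("winner by precedence: %s", winner))
  sub <- assign_subgroup(winner, pool)
  list(diagnosis = winner, subgroup = sub,
       assignment_trace = c(trace, sprintf("subgroup: %s", sub)))
}

#' Assign the diagnosis subgroup from a concept pool
#'
#' Per-diagnosis rules are evaluated in ruleset order; the residual subgroup
#' (last rule, unconditional) applies when no modifier marker is present.
#'
#' @param diagnosis a sentinel diagnosis (not `"none"`).
#' @param concepts pooled concept character vector.
#' @param ruleset a `chd_ruleset`.
#' @return subgroup name.
#' @export
assign_subgroup <- function(diagnosis, concepts, ruleset = load_ruleset()) {
  stopifnot(diagnosis != "none")
  rules <- ruleset$subgroup_rules[[diagnosis]]
  if (is.null(rules)) stopf("no subgroup rules for diagnosis %s", diagnosis)
  for (rule in rules) {
    any_of <- unlist(rule$any_of) %||% character(0)
    all_of <- unlist(rule$all_of) %||% character(0)
    if ((!length(any_of) || any(any_of %in% concepts)) &&
        (!length(all_of) || all(all_of %in% concepts))) {
      return(rule$subgroup)
    }
  }
  stopf("no subgroup rule matched for %s", diagnosis)  # unreachable: residual
}

#' Derive complexity flags (prematurity, congenital comorbidity)
#'
#' TRUE iff any record of the patient carries a matching concept.
#'
#' @param history a patient history.
#' @param dictionary a [concept_dictionary()].
#' @return list with logical `prematurity` and `comorbidity`.
#' @export
derive_complexity_flags <- function(history, dictionary) {
  pool <- pooled_concepts(history$records)
  list(prematurity = any(pool %in% dictionary$prematurity_concepts),
       comorbidity = any(pool %in% dictionary$comorbidity_concepts))
}

#' Vectorized phenotyping over a linked cohort
#'
#' @param cohort a `chd_cohort`.
#' @param dictionary a [concept_dictionary()].
#' @param ruleset a `chd_ruleset`.
#' @return data.frame with one row per patient: diagnosis, subgroup,
#'   candidates, prematurity, comorbidity.
#' @export
assign_diagnoses <- function(cohort, dictionary = default_concept_dictionary(),
                             ruleset = load_ruleset()) {
  rec <- cohort$procedures
  patients <- cohort$patients
  pidx <- match(rec$patient_id, patients)

  cells <- paste(rec$diagnosis_concepts, rec$procedure_concepts, sep = ";")
  raw <- strsplit(cells, ";", fixed = TRUE)
  lens <- lengths(raw)
  concept <- unlist(raw, use.names = FALSE)
  owner <- rep.int(pidx, lens)
  keep <- nzchar(concept)
  concept <- concept[keep]; owner <- owner[keep]
  pairs <- !duplicated(paste0(owner, "\r", concept))
  concept <- concept[pairs]; owner <- owner[pairs]

  n <- length(patients)
  has_concept <- function(cid) {
    out <- logical(n)
    out[owner[concept == cid]] <- TRUE
    out
  }

  # Candidate diagnoses by precedence rank; none if no sentinel marker.
  marker <- dictionary$diagnosis_markers[concept]
  rank <- match(marker, ruleset$precedence)  # NA for not_sentinel / no marker
  best <- rep(NA_integer_, n)
  ok <- !is.na(rank)
  if (any(ok)) {
    agg <- tapply(rank[ok], owner[ok], min)
    best[as.integer(names(agg))] <- as.integer(agg)
  }
  diagnosis <- ifelse(is.na(best), "none", ruleset$precedence[best])

  n_cand <- integer(n)
  if (any(ok)) {
    cand_pairs <- !duplicated(paste0(owner[ok], "\r", rank[ok]))
    tab <- table(owner[ok][cand_pairs])
    n_cand[as.integer(names(tab))] <- as.integer(tab)
  }

  # Subgroups: evaluate rule conditions vectorized per diagnosis.
  concept_flags <- new.env(parent = emptyenv())
  flag <- function(cid) {
    if (is.null(concept_flags[[cid]])) concept_flags[[cid]] <- has_concept(cid)
    concept_flags[[cid]]
  }
  subgroup <- rep(NA_character_, n)
  for (dx in unique(diagnosis[diagnosis != "none"])) {
    in_dx <- diagnosis == dx
    unset <- in_dx
    for (rule in ruleset$subgroup_rules[[dx]]) {
      any_of <- unlist(rule$any_of) %||% character(0)
      all_of <- unlist(rule$all_of) %||% character(0)
      cond <- rep(TRUE, n)
      if (length(any_of)) {
        cond <- Reduce(`|`, lapply(any_of, flag))
      }
      if (length(all_of)) {
        cond <- cond & Reduce(`&`, lapply(all_of, flag))
      }
      hit <- unset & cond
      subgroup[hit] <- rule$subgroup
      unset <- unset & !hit
    }
  }

  prem <- Reduce(`|`, lapply(dictionary$prematurity_concepts, flag),
                 accumulate = FALSE) %||% logical(n)
  com <- Reduce(`|`, lapply(dictionary$comorbidity_concepts, flag),
                accumulate = FALSE) %||% logical(n)

  data.frame(patient_id = patients, diagnosis = diagnosis,
             subgroup = subgroup, n_candidates = n_cand,
             prematurity = prem, comorbidity = com,
             stringsAsFactors = FALSE)
}

EXCLUSION_REASONS <- c("born_outside_window", "outside_england_wales",
                       "non_nhs", "no_cardiac_codes", "major_data_error",
                       "not_sentinel")

#' Apply cohort inclusion/exclusion rules
#'
#' Reasons are checked in fixed order: born outside the study window,
#' resident outside England and Wales, non-NHS patient, no cardiac procedure
#' codes, major data error, not a sentinel diagnosis. The first matching
#' reason is reported.
#'
#' @param cohort a `chd_cohort`.
#' @param diagnoses phenotyping table from [assign_diagnoses()].
#' @return data.frame with patient_id, excluded (logical), reason.
#' @export
apply_exclusions <- function(cohort, diagnoses) {
  rec <- cohort$procedures
  patients <- cohort$patients
  pidx <- match(rec$patient_id, patients)
  n <- length(patients)

  agg_any <- function(x) {
    out <- logical(n)
    hit <- unique(pidx[x])
    out[hit] <- TRUE
    out
  }
  born_out <- agg_any(!rec$born_in_window)
  idx_first <- which(!duplicated(pidx))
  res_first <- rep(NA_character_, n)
  res_first[pidx[idx_first]] <- rec$residency[idx_first]
  outside <- res_first == "other"
  non_nhs <- res_first == "non_nhs"
  has_proc_codes <- agg_any(nzchar(rec$procedure_concepts))
  data_err <- agg_any(isTRUE_vec(rec$discharge_error))
  not_sent <- diagnoses$diagnosis[match(patients, diagnoses$patient_id)] == "none"

  reason <- rep(NA_character_, n)
  pick <- function(cond, why) reason[is.na(reason) & cond] <<- why
  pick(born_out, "born_outside_window")
  pick(outside, "outside_england_wales")
  pick(non_nhs, "non_nhs")
  pick(!has_proc_codes, "no_cardiac_codes")
  pick(data_err, "major_data_error")
  pick(not_sent, "not_sentinel")

  data.frame(patient_id = patients, excluded = !is.na(reason),
             reason = reason, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x
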