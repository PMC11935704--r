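# Outcome ascertainment and metric computation: life-status precedence,
# per-patient event histories, Kaplan-Meier survival and competing-risks
# reintervention incidence at the report ages, plus scoping metrics.

#' Ascertain life status for every patient in a cohort
#'
#' Precedence: age at death recorded by the procedure audit (NCHDA), then
#' age at death from the national mortality register (ONS), then the ONS
#' alive-confirmation age (censoring). Patients with no mortality-register
#' information are deemed lost to follow-up and censored at their most
#' recent discharge age.
#'
#' @param cohort a `chd_cohort`.
#' @return data.frame: patient_id, terminal_kind ("death"/"censor"),
#'   terminal_age_days, source, ltfu, resolvable.
#' @export
ascertain_life <- function(cohort) {
  life <- cohort$life
  rec <- cohort$procedures
  patients <- cohort$patients
  pidx <- match(rec$patient_id, patients)
  n <- length(patients)

  last_disch <- rep(NA_real_, n)
  ok <- !is.na(rec$discharge_age_days)
  if (any(ok)) {
    agg <- tapply(rec$discharge_age_days[ok], pidx[ok], max)
    last_disch[as.integer(names(agg))] <- agg
  }
  # fall back to the last procedure age if no discharge age was recorded
  agg2 <- tapply(rec$age_days, pidx, max)
  last_proc <- rep(NA_real_, n)
  last_proc[as.integer(names(agg2))] <- agg2
  last_disch <- ifelse(is.na(last_disch), last_proc, last_disch)

  m <- match(patients, life$patient_id)
  nchda <- life$nchda_death_age_days[m]
  ons_d <- life$ons_death_age_days[m]
  ons_c <- life$ons_alive_confirm_age_days[m]

  kind <- rep(NA_character_, n)
  age <- rep(NA_real_, n)
  source <- rep(NA_character_, n)
  ltfu <- rep(FALSE, n)

  take <- function(cond, k, a, src) {
    sel <- is.na(kind) & cond & !is.na(a)
    kind[sel] <<- k; age[sel] <<- a[sel]; source[sel] <<- src
  }
  take(TRUE, "death", nchda, "nchda")
  take(TRUE, "death", ons_d, "ons")
  take(TRUE, "censor", ons_c, "ons_confirm")
  sel <- is.na(kind) & !is.na(last_disch)
  kind[sel] <- "censor"; age[sel] <- last_disch[sel]
  source[sel] <- "discharge"; ltfu[sel] <- TRUE

  data.frame(patient_id = patients, terminal_kind = kind,
             terminal_age_days = age, source = source, ltfu = ltfu,
             resolvable = !is.na(kind), stringsAsFactors = FALSE)
}

#' Ascertain life status for one patient
#'
#' @param history a patient history (records plus life status).
#' @return list with `terminal_kind`, `terminal_age_days`, `source`, `ltfu`.
#' @export
ascertain_life_status <- function(history) {
  cohort <- structure(list(procedures = history$records,
                           life = history$life_status,
                           patients = history$patient_id),
                      class = "chd_cohort")
  out <- ascertain_life(cohort)
  if (!out$resolvable) stopf("patient %s: no resolvable life-status age",
                             history$patient_id)
  list(terminal_kind = out$terminal_kind,
       terminal_age_days = out$terminal_age_days,
       source = out$source, ltfu = out$ltfu)
}

#' Build per-patient event histories for the outcome metrics
#'
#' Follow-up for the reintervention analyses ends at the first
#' reintervention, death, transplant, or censoring, whichever comes first;
#' death and heart transplant without prior reintervention are the competing
#' event. Ties between a reintervention and death at the same age resolve as
#' reintervention. For the type-specific analyses (surgical / catheter) the
#' first reintervention of that type is the event and death/transplant the
#' competing event.
#'
#' @param diagnoses phenotyping table.
#' @param pathways result of [assign_pathways()].
#' @param life_asc result of [ascertain_life()].
#' @param flags result of [flag_patients()] (may be NULL).
#' @return data.frame, one row per resolvable patient.
#' @export
build_event_histories <- function(diagnoses, pathways, life_asc,
                                  flags = NULL) {
  a <- pathways$assignments
  r <- pathways$reinterventions
  patients <- a$patient_id
  n <- length(patients)

  first_reint <- function(sub) {
    out <- rep(NA_real_, n)
    if (nrow(sub)) {
      agg <- tapply(sub$age_days, match(sub$patient_id, patients), min)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  fr_any <- first_reint(r)
  fr_surg <- first_reint(r[r$category == "surgical", , drop = FALSE])
  fr_cath <- first_reint(r[r$category == "catheter", , drop = FALSE])

  m <- match(patients, life_asc$patient_id)
  kind <- life_asc$terminal_kind[m]
  term <- life_asc$terminal_age_days[m]
  ltfu <- life_asc$ltfu[m]
  death <- ifelse(!is.na(kind) & kind == "death", term, Inf)

  bad <- which(!is.na(fr_any) & fr_any > death)
  if (length(bad)) {
    stopf("reintervention recorded after death for patient(s): %s",
          paste(patients[bad], collapse = ", "))
  }

  tx <- ifelse(is.na(a$transplant_age_days), Inf, a$transplant_age_days)
  censor <- ifelse(!is.na(kind) & kind == "censor", term, Inf)
  competing <- pmin(death, tx)

  mk_endpoint <- function(fr) {
    ev_time <- pmin(fr, competing, censor, na.rm = TRUE)
    event <- integer(n)
    event[!is.na(fr) & fr <= pmin(competing, censor)] <- 1L
    event[event == 0L & competing <= censor & is.finite(competing)] <- 2L
    list(time = ev_time, event = event)
  }
  any_ep <- mk_endpoint(fr_any)
  surg_ep <- mk_endpoint(fr_surg)
  cath_ep <- mk_endpoint(fr_cath)

  mdx <- match(patients, diagnoses$patient_id)
  flagged <- if (is.null(flags)) rep(FALSE, n) else
    isTRUE_vec(flags$flagged[match(patients, flags$patient_id)])

  out <- data.frame(
    patient_id = patients,
    diagnosis = diagnoses$diagnosis[mdx],
    subgroup = diagnoses$subgroup[mdx],
    flagged = flagged,
    terminal_kind = kind, terminal_age_days = term, ltfu = ltfu,
    surv_time = term, surv_event = as.integer(!is.na(kind) & kind == "death"),
    time_any = any_ep$time, event_any = any_ep$event,
    time_surgical = surg_ep$time, event_surgical = surg_ep$event,
    time_catheter = cath_ep$time, event_catheter = cath_ep$event,
    stringsAsFactors = FALSE)
  out[!is.na(kind), , drop = FALSE]
}

quantile_stats <- function(x) {
  if (!length(x)) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
             min = NA_real_, max = NA_real_))
  }
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3], min = min(x), max = max(x))
}

metrics_row <- function(eh, label_level, dx, sub, report_ages,
                        exclude_flagged_reint = TRUE) {
  n <- nrow(eh)
  ages_y <- days_to_years(report_ages)
  km <- km_survival(eh$surv_time, eh$surv_event, report_ages)
  fu <- quantile_stats(days_to_years(eh$surv_time))

  ehr <- if (exclude_flagged_reint) eh[!eh$flagged, , drop = FALSE] else eh
  cif_block <- function(time_col, event_col, prefix) {
    if (!nrow(ehr)) {
      out <- as.list(rep(NA_real_, 3 * length(report_ages)))
    } else {
      fit <- cif_competing(ehr[[time_col]], ehr[[event_col]],
                           report_ages = report_ages)
      rep1 <- fit$report[fit$report$cause == "reintervention", ]
      out <- c(as.list(rep1$cif), as.list(rep1$lower), as.list(rep1$upper))
    }
    names(out) <- c(sprintf("%s_%gy", prefix, ages_y),
                    sprintf("%s_lo_%gy", prefix, ages_y),
                    sprintf("%s_hi_%gy", prefix, ages_y))
    out
  }

  fu_reint <- quantile_stats(days_to_years(ehr$time_any))

  cbind(
    data.frame(level = label_level, diagnosis = dx, subgroup = sub,
               n = n, n_reint_analysis = nrow(ehr),
               fu_median = fu["median"], fu_q1 = fu["q1"], fu_q3 = fu["q3"],
               fu_min = fu["min"], fu_max = fu["max"],
               reint_fu_median = fu_reint["median"],
               reint_fu_q1 = fu_reint["q1"], reint_fu_q3 = fu_reint["q3"],
               reint_fu_min = fu_reint["min"], reint_fu_max = fu_reint["max"],
               stringsAsFactors = FALSE, row.names = NULL),
    stats::setNames(data.frame(as.list(km$report$surv), as.list(km$report$lower),
                               as.list(km$report$upper)),
                    c(sprintf("surv_%gy", ages_y),
                      sprintf("surv_lo_%gy", ages_y),
                      sprintf("surv_hi_%gy", ages_y))),
    data.frame(cif_block("time_any", "event_any", "reint_any")),
    data.frame(cif_block("time_surgical", "event_surgical", "reint_surgical")),
    data.frame(cif_block("time_catheter", "event_catheter", "reint_catheter")))
}

#' Outcome metric table per diagnosis and subgroup
#'
#' One row per diagnosis and one per subgroup: n, follow-up summaries,
#' Kaplan-Meier survival with 95% CI at the report ages, and cumulative
#' incidence of reintervention (any / surgical / catheter) with 95% CI,
#' death and transplant treated as competing events. Quality-flagged
#' patients are excluded from the reintervention estimates (but retained for
#' survival). Empty groups are omitted.
#'
#' @param event_histories from [build_event_histories()].
#' @param report_ages report ages in days.
#' @param exclude_flagged_reint exclude flagged patients from reintervention
#'   metrics (default TRUE).
#' @return data.frame with estimates as proportions (multiply by 100 and
#'   round to one decimal for display).
#' @export
metrics_table <- function(event_histories,
                          report_ages = report_ages_default(),
                          exclude_flagged_reint = TRUE) {
  eh <- event_histories
  rows <- list()
  for (dx in intersect(SENTINEL_DIAGNOSES, unique(eh$diagnosis))) {
    sub_dx <- eh[eh$diagnosis == dx, , drop = FALSE]
    if (!nrow(sub_dx)) next
    rows[[length(rows) + 1L]] <-
      metrics_row(sub_dx, "diagnosis", dx, NA_character_, report_ages,
                  exclude_flagged_reint)
    for (sg in sort(unique(sub_dx$subgroup))) {
      sub_sg <- sub_dx[sub_dx$subgroup == sg, , drop = FALSE]
      if (!nrow(sub_sg)) next
      rows[[length(rows) + 1L]] <-
        metrics_row(sub_sg, "subgroup", dx, sg, report_ages,
                    exclude_flagged_reint)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scoping metrics per diagnosis
#'
#' For each diagnosis: the number of patients, the proportion starting
#' interventional treatment in infancy (first procedure before age 1 year),
#' the proportion with three or more cardiac procedures, and the proportion
#' who died before age 5 years.
#'
#' @param cohort a `chd_cohort`.
#' @param diagnoses phenotyping table.
#' @param life_asc from [ascertain_life()].
#' @return data.frame: diagnosis, n, pct_infancy, pct_3plus, pct_died_lt5y.
#' @export
scoping_metrics <- function(cohort, diagnoses, life_asc) {
  rec <- cohort$procedures
  patients <- cohort$patients
  pidx <- match(rec$patient_id, patients)
  first_age <- rep(NA_real_, length(patients))
  agg <- tapply(rec$age_days, pidx, min)
  first_age[as.integer(names(agg))] <- agg
  n_proc <- tabulate(pidx, nbins = length(patients))

  m <- match(patients, life_asc$patient_id)
  died5 <- !is.na(life_asc$terminal_kind[m]) &
    life_asc$terminal_kind[m] == "death" &
    life_asc$terminal_age_days[m] < years_to_days(5)

  dxv <- diagnoses$diagnosis[match(patients, diagnoses$patient_id)]
  out <- do.call(rbind, lapply(intersect(SENTINEL_DIAGNOSES, unique(dxv)),
    function(dx) {
      sel <- dxv == dx
      data.frame(diagnosis = dx, n = sum(sel),
                 pct_infancy = pct1(sum(first_age[sel] < years_to_days(1),
                                        na.rm = TRUE), sum(sel)),
                 pct_3plus = pct1(sum(n_proc[sel] >= 3), sum(sel)),
                 pct_died_lt5y = pct1(sum(died5[sel]), sum(sel)),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}
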