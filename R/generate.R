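# Synthetic registry generation: seeded cohorts with the statistical
# structure the downstream analysis assumes, plus ground truth enabling
# parameter-recovery and classification-recovery tests.

PROC_CODE <- c(bas = "120101", norwood = "120201", hybrid = "120301",
               shunt = "120401", band = "120501", glenn = "120601",
               fontan = "120701", switch = "120801", tof_repair = "120901",
               avsd_repair = "121001", vsd_closure = "121101",
               coarct_repair = "121201", aortic_valvuloplasty = "121301",
               pa_repair = "121401", transplant = "121501", cath = "130101",
               misc_surgery = "130201")

DX_CODE <- c(HLHS = "010101", FUH = "010201", TGA = "010301", PA = "010401",
             AVSD = "010501", TOF = "010601", AS = "010701",
             COARCT = "010801", VSD = "010901")

SUBGROUP_MOD_CODES <- list(
  HLHS = list(hlhs = character(0)),
  FUH = list(double_inlet_ventricle = "020101", tricuspid_atresia = "020201"),
  TGA = list(complex_with_PS = c("020301", "020401"),
             complex_without_PS = "020301", intact_septum = character(0)),
  PA = list(with_VSD = "010901", intact_septum = character(0)),
  AVSD = list(tetralogy_AVSD = "010601", unbalanced = "020501",
              partial = "020601", complete = character(0)),
  TOF = list(absent_pulm_valve = "020801", DORV = "020701",
             standard = character(0)),
  AS = list(multilevel_LHO = "020901", isolated = character(0)),
  COARCT = list(with_VSD = "010901", isolated = character(0)),
  VSD = list(multiple = "021001", isolated = character(0)))

REPAIR_EMIT <- list(
  TGA = c(code = "120801", modality = "bypass_surgery"),
  PA = c(code = "121401", modality = "bypass_surgery"),
  AVSD = c(code = "121001", modality = "bypass_surgery"),
  TOF = c(code = "120901", modality = "bypass_surgery"),
  AS = c(code = "121301", modality = "catheter"),
  COARCT = c(code = "121201", modality = "nonbypass_surgery"),
  VSD = c(code = "121101", modality = "bypass_surgery"))

empty_procedures_df <- function() {
  data.frame(patient_id = character(0), age_days = integer(0),
             procedure_codes = character(0), diagnosis_codes = character(0),
             modality = character(0), discharge_age_days = integer(0),
             center_id = character(0), residency = character(0),
             born_in_window = character(0), stringsAsFactors = FALSE)
}

empty_life_df <- function() {
  data.frame(patient_id = character(0), nchda_death_age_days = integer(0),
             ons_death_age_days = integer(0),
             ons_alive_confirm_age_days = integer(0), stringsAsFactors = FALSE)
}

empty_truth_df <- function() {
  data.frame(patient_id = character(0), diagnosis = character(0),
             subgroup = character(0), sv_pathway = logical(0),
             prematurity = logical(0), comorbidity = logical(0),
             weight_kg = numeric(0), age_first_days = integer(0),
             horizon_days = numeric(0), death_age_days = numeric(0),
             tx_age_days = numeric(0), terminal_days = numeric(0),
             ltfu = logical(0), prepathway_age = integer(0),
             stage1_age = integer(0), stage2_age = integer(0),
             stage3_age = integer(0), repair_age = integer(0),
             transplant_age = integer(0), corrupted = logical(0),
             corruption_op = character(0), stringsAsFactors = FALSE)
}

empty_reint_truth_df <- function() {
  data.frame(patient_id = character(0), age_days = integer(0),
             modality = character(0), category = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic cohort
#'
#' Deterministic given the seed: each diagnosis block draws from its own
#' sub-stream derived from the master seed and the block name, so editing one
#' block does not reshuffle the others. Every patient has at least one
#' procedure record; staged patients attain stages in order; death,
#' transplant and the follow-up horizon truncate subsequent procedures.
#' Corruption (per `spec$global$corruption_rate`) is applied through
#' [inject_data_issues()].
#'
#' @param spec a [cohort_spec()].
#' @param seed integer master seed.
#' @param dictionary concept dictionary used to emit raw codes and to target
#'   corruption operations.
#' @return An object of class `chd_simulation`: list with `procedures` (raw
#'   registry CSV dialect), `life`, `truth` (list of `patients` and
#'   `reinterventions` data.frames), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed,
                            dictionary = default_concept_dictionary()) {
  validate_cohort_spec(spec)
  parts <- lapply(names(spec$blocks), function(dx) {
    gen_block(dx, spec$blocks[[dx]], spec$global, derive_seed(seed, dx))
  })
  records <- do.call(rbind, c(lapply(parts, `[[`, "records"),
                              list(empty_procedures_df())))
  life <- do.call(rbind, c(lapply(parts, `[[`, "life"),
                           list(empty_life_df())))
  truth <- list(
    patients = do.call(rbind, c(lapply(parts, `[[`, "patients"),
                                list(empty_truth_df()))),
    reinterventions = do.call(rbind, c(lapply(parts, `[[`, "reints"),
                                       list(empty_reint_truth_df()))))
  rownames(records) <- NULL
  rownames(truth$patients) <- NULL
  rownames(truth$reinterventions) <- NULL

  rate <- spec$global$corruption_rate
  if (rate > 0 && nrow(truth$patients)) {
    injected <- inject_data_issues(records, truth, rate,
                                   derive_seed(seed, "corruption"), dictionary)
    records <- injected$records
    truth <- injected$truth
  }
  structure(list(procedures = records, life = life, truth = truth,
                 spec = spec, seed = seed),
            class = "chd_simulation")
}

gen_block <- function(dx, blk, g, seed) {
  n <- as.integer(blk$n)
  if (n == 0L) {
    return(list(records = empty_procedures_df(), life = empty_life_df(),
                patients = empty_truth_df(), reints = empty_reint_truth_df()))
  }
  set.seed(seed)
  q75 <- 2 * stats::qnorm(0.75)
  pid <- sprintf("%s-%05d", dx, seq_len(n))
  subgroup <- sample(names(blk$subgroup_mix), n, replace = TRUE,
                     prob = blk$subgroup_mix)
  horizon <- stats::runif(n, g$followup_years[1], g$followup_years[2]) *
    DAYS_PER_YEAR
  sd_age <- (log(blk$age_first[3]) - log(pmax(blk$age_first[2], 0.5))) / q75
  age_first <- pmax(0, round(stats::rlnorm(n, log(blk$age_first[1]), sd_age)))
  sd_wt <- (log(blk$weight[3]) - log(blk$weight[2])) / q75
  weight <- round(stats::rlnorm(n, log(blk$weight[1]), sd_wt), 2)
  prem <- stats::runif(n) < blk$prematurity_rate
  com <- stats::runif(n) < blk$comorbidity_rate
  death <- pmax(1, ceiling(sample_pw_exp(n, blk$death_hazard) * DAYS_PER_YEAR))
  tx <- ceiling(sample_pw_exp(n, rep(blk$tx_rate %||% 0, 4)) * DAYS_PER_YEAR)
  # Loss to follow-up is a loss *time* (e.g. emigration): after it neither
  # procedures nor life status are observed, so downstream censoring stays
  # independent of the death and reintervention processes.
  ltfu <- stats::runif(n) < g$ltfu_rate
  loss <- ifelse(ltfu, stats::runif(n, 0, horizon), Inf)
  obs_end <- pmin(horizon, loss)
  end <- pmin(death, tx, obs_end)
  afe <- as.integer(pmax(0, pmin(age_first, death - 1, tx - 1,
                                 floor(obs_end))))

  sv <- stats::runif(n) < blk$sv_fraction
  pre <- stats::runif(n) < blk$prepathway_prob
  gp <- function(med) pmax(1, round(stats::rlnorm(n, log(med), g$gap_sdlog)))
  main1 <- afe + ifelse(pre, gp(GAP_MEDIANS["pre"]), 0)

  a1 <- sv & stats::runif(n) < blk$sv_attain[1]
  s1_age <- main1
  s2_age <- s1_age + gp(GAP_MEDIANS["s12"])
  a2 <- a1 & stats::runif(n) < blk$sv_attain[2]
  s3_age <- s2_age + gp(GAP_MEDIANS["s23"])
  a3 <- a2 & stats::runif(n) < blk$sv_attain[3]

  b1 <- !sv & stats::runif(n) < blk$bv_stage1_prob
  brep <- !sv & stats::runif(n) < blk$bv_repair_prob
  b1_age <- main1
  brep_age <- ifelse(b1, main1 + gp(GAP_MEDIANS["s1rep"]), main1)

  s1_keep <- a1 & s1_age <= end
  s2_keep <- a2 & s2_age <= end
  s3_keep <- a3 & s3_age <= end
  b1_keep <- b1 & b1_age <= end
  brep_keep <- brep & brep_age <= end
  tx_keep <- is.finite(tx) & tx <= pmin(death, obs_end)

  # Reintervention process: thinned Poisson under the piecewise hazard,
  # truncated at death/transplant/horizon.
  lmax <- max(blk$reint_hazard)
  r_pid <- integer(0); r_age <- integer(0); r_surg <- logical(0)
  if (lmax > 0) {
    end_y <- end / DAYS_PER_YEAR
    nev <- stats::rpois(n, lmax * end_y)
    if (sum(nev)) {
      idx <- rep.int(seq_len(n), nev)
      t_y <- stats::runif(sum(nev), 0, end_y[idx])
      acc <- stats::runif(sum(nev)) <
        blk$reint_hazard[findInterval(t_y, HAZARD_BREAKS_YEARS)] / lmax
      idx <- idx[acc]; t_y <- t_y[acc]
      age <- round(t_y * DAYS_PER_YEAR)
      ok <- age <= end[idx] & age >= 0
      r_pid <- idx[ok]; r_age <- as.integer(age[ok])
      r_surg <- stats::runif(length(r_pid)) < blk$reint_surgical_share
    }
  }

  has_any <- pre | s1_keep | s2_keep | s3_keep | b1_keep | brep_keep |
    tx_keep | seq_len(n) %in% r_pid
  pre_eff <- pre | !has_any

  # Stage-1 emission: diagnosis-specific procedure subtype and modality.
  stage1_emit <- function(which_idx) {
    k <- length(which_idx)
    if (dx == "HLHS") {
      hybrid <- stats::runif(k) < 0.12
      list(code = ifelse(hybrid, PROC_CODE["hybrid"], PROC_CODE["norwood"]),
           modality = ifelse(hybrid, "hybrid", "bypass_surgery"))
    } else if (dx == "VSD") {
      list(code = rep(PROC_CODE[["band"]], k),
           modality = rep("nonbypass_surgery", k))
    } else {
      list(code = rep(PROC_CODE[["shunt"]], k),
           modality = rep("nonbypass_surgery", k))
    }
  }

  ev <- list()
  add_ev <- function(idx, age, code, modality, prio) {
    if (!length(idx)) return()
    ev[[length(ev) + 1L]] <<- data.frame(
      i = idx, age = as.integer(age), code = as.character(code),
      modality = as.character(modality), prio = prio,
      stringsAsFactors = FALSE)
  }
  add_ev(which(pre_eff), afe[pre_eff], PROC_CODE[["bas"]], "catheter", 1L)
  s1_idx <- which(s1_keep | b1_keep)
  if (length(s1_idx)) {
    em <- stage1_emit(s1_idx)
    add_ev(s1_idx, ifelse(s1_keep[s1_idx], s1_age[s1_idx], b1_age[s1_idx]),
           em$code, em$modality, 2L)
  }
  add_ev(which(s2_keep), s2_age[s2_keep], PROC_CODE[["glenn"]],
         "bypass_surgery", 3L)
  add_ev(which(s3_keep), s3_age[s3_keep], PROC_CODE[["fontan"]],
         "bypass_surgery", 4L)
  rep_idx <- which(brep_keep)
  if (length(rep_idx)) {
    em <- REPAIR_EMIT[[dx]]
    add_ev(rep_idx, brep_age[rep_idx], em[["code"]], em[["modality"]], 5L)
  }
  add_ev(which(tx_keep), tx[tx_keep], PROC_CODE[["transplant"]],
         "bypass_surgery", 6L)
  add_ev(r_pid, r_age,
         ifelse(r_surg, PROC_CODE[["misc_surgery"]], PROC_CODE[["cath"]]),
         ifelse(r_surg, "nonbypass_surgery", "catheter"), 7L)

  evd <- do.call(rbind, ev)
  evd <- evd[order(evd$i, evd$age, evd$prio, method = "radix"), , drop = FALSE]

  dx_codes_patient <- vapply(seq_len(n), function(i) {
    join_codes(c(DX_CODE[[dx]], SUBGROUP_MOD_CODES[[dx]][[subgroup[i]]]))
  }, character(1))
  center <- sample(sprintf("C%02d", seq_len(g$n_centers)), n, replace = TRUE)
  residency <- sample(names(g$residency_mix), n, replace = TRUE,
                      prob = g$residency_mix)

  diag_codes <- dx_codes_patient[evd$i]
  first_row <- !duplicated(evd$i)
  extra <- ifelse(prem[evd$i] & first_row, ";030201", "")
  extra <- paste0(extra, ifelse(com[evd$i] & first_row, ";030101", ""))
  diag_codes <- paste0(diag_codes, extra)

  records <- data.frame(
    patient_id = pid[evd$i],
    age_days = evd$age,
    procedure_codes = evd$code,
    diagnosis_codes = diag_codes,
    modality = evd$modality,
    discharge_age_days = evd$age + sample(7:21, nrow(evd), replace = TRUE),
    center_id = center[evd$i],
    residency = residency[evd$i],
    born_in_window = "TRUE",
    stringsAsFactors = FALSE)

  # Life status: NCHDA/ONS precedence sources. Deaths are observed only
  # while the patient is under observation (before the horizon and any loss
  # time); lost patients have no ONS columns, and a death occurring before
  # the loss appears in the procedure audit only.
  died_obs <- death <= obs_end
  src <- sample(names(g$death_source_mix), n, replace = TRUE,
                prob = g$death_source_mix)
  nchda_death <- ifelse(died_obs & (ltfu | src %in% c("both", "nchda_only")),
                        death, NA_real_)
  ons_death <- ifelse(died_obs & !ltfu & src %in% c("both", "ons_only"),
                      death, NA_real_)
  confirm <- ifelse(!died_obs & !ltfu, floor(horizon), NA_real_)
  has_life_row <- !is.na(nchda_death) | !is.na(ons_death) | !is.na(confirm)
  life <- data.frame(patient_id = pid,
                     nchda_death_age_days = as.integer(nchda_death),
                     ons_death_age_days = as.integer(ons_death),
                     ons_alive_confirm_age_days = as.integer(confirm),
                     stringsAsFactors = FALSE)[has_life_row, , drop = FALSE]

  slot_age <- function(keep, age) ifelse(keep, as.integer(age), NA_integer_)
  patients <- data.frame(
    patient_id = pid, diagnosis = dx, subgroup = subgroup,
    sv_pathway = sv, prematurity = prem, comorbidity = com,
    weight_kg = weight, age_first_days = afe,
    horizon_days = horizon, death_age_days = death, tx_age_days = tx,
    terminal_days = end, ltfu = ltfu,
    prepathway_age = slot_age(pre_eff, afe),
    stage1_age = slot_age(s1_keep | b1_keep,
                          ifelse(s1_keep, s1_age, b1_age)),
    stage2_age = slot_age(s2_keep, s2_age),
    stage3_age = slot_age(s3_keep, s3_age),
    repair_age = slot_age(brep_keep, brep_age),
    transplant_age = slot_age(tx_keep, tx),
    corrupted = FALSE, corruption_op = NA_character_,
    stringsAsFactors = FALSE)

  reints <- data.frame(
    patient_id = pid[r_pid], age_days = r_age,
    modality = ifelse(r_surg, "nonbypass_surgery", "catheter"),
    category = ifelse(r_surg, "surgical", "catheter"),
    stringsAsFactors = FALSE)
  ord <- order(reints$patient_id, reints$age_days, method = "radix")
  reints <- reints[ord, , drop = FALSE]

  list(records = records, life = life, patients = patients, reints = reints)
}

#' Inject data-quality issues into a synthetic cohort
#'
#' Selects patients with probability `corruption_rate` and corrupts their
#' procedure sequence. The default policy picks, per patient, an operation
#' that produces a sequence implausible for the diagnosis: deleting the
#' stage-1 record while keeping stage 2, inserting a staged-palliation record
#' into an exclusively biventricular history, or inserting a Fontan-type
#' record with no preceding Glenn. `ops = "duplicate_repair"` instead
#' duplicates the reparative procedure as an unlabeled same-day row.
#'
#' @param records raw procedure records (registry CSV dialect).
#' @param truth ground-truth list from [generate_cohort()].
#' @param corruption_rate probability in `[0, 1]`.
#' @param seed integer seed.
#' @param dictionary concept dictionary (used to locate role-bearing rows).
#' @param ops `"auto"` (default detectable policy) or `"duplicate_repair"`.
#' @return list with updated `records` and `truth` (corruption labels set).
#' @export
inject_data_issues <- function(records, truth, corruption_rate, seed,
                               dictionary = default_concept_dictionary(),
                               ops = "auto") {
  stopifnot(corruption_rate >= 0, corruption_rate <= 1)
  if (corruption_rate == 0 || !nrow(truth$patients)) {
    return(list(records = records, truth = truth))
  }
  set.seed(seed)
  pts <- truth$patients
  sel <- which(stats::runif(nrow(pts)) < corruption_rate)
  if (!length(sel)) return(list(records = records, truth = truth))

  bv_only <- c("TOF", "AS", "COARCT", "VSD")
  rows_by_pid <- split(seq_len(nrow(records)), records$patient_id)
  drop_rows <- integer(0)
  new_rows <- list()

  for (i in sel) {
    id <- pts$patient_id[i]
    dx <- pts$diagnosis[i]
    rows <- rows_by_pid[[id]]
    first_code <- vapply(records$procedure_codes[rows],
                         function(s) split_codes(s)[1], character(1))
    concepts <- unname(dictionary$code_to_concept[first_code])
    roles <- concept_role(concepts, dx, dictionary)

    insert <- function(code) {
      last_age <- max(records$age_days[rows])
      ins_age <- as.integer(max(last_age,
                                min(last_age + 180, pts$terminal_days[i])))
      r1 <- rows[1]
      new_rows[[length(new_rows) + 1L]] <<- data.frame(
        patient_id = id, age_days = ins_age, procedure_codes = code,
        diagnosis_codes = gsub(";03[0-9]{4}", "", records$diagnosis_codes[r1]),
        modality = "bypass_surgery",
        discharge_age_days = ins_age + 14L,
        center_id = records$center_id[r1],
        residency = records$residency[r1],
        born_in_window = records$born_in_window[r1],
        stringsAsFactors = FALSE)
    }

    if (identical(ops, "duplicate_repair")) {
      rep_rows <- rows[roles == "repair"]
      if (!length(rep_rows)) next
      r <- rep_rows[1]
      dup <- records[r, , drop = FALSE]
      dup$procedure_codes <- PROC_CODE[["misc_surgery"]]
      new_rows[[length(new_rows) + 1L]] <- dup
      op <- "duplicate_repair"
    } else if (any(roles == "stage1") && any(roles == "stage2")) {
      drop_rows <- c(drop_rows, rows[roles == "stage1"])
      op <- "drop_stage1"
    } else if (any(roles == "stage2") && any(roles == "stage3")) {
      drop_rows <- c(drop_rows, rows[roles == "stage2"])
      op <- "drop_stage2"
    } else if (dx %in% bv_only || any(roles == "repair")) {
      insert(PROC_CODE[["glenn"]])
      op <- "insert_stage2"
    } else {
      insert(PROC_CODE[["fontan"]])
      op <- "insert_stage3"
    }
    pts$corrupted[i] <- TRUE
    pts$corruption_op[i] <- op
  }

  if (length(drop_rows)) records <- records[-drop_rows, , drop = FALSE]
  if (length(new_rows)) records <- rbind(records, do.call(rbind, new_rows))
  ord <- order(records$patient_id, records$age_days, method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  truth$patients <- pts
  list(records = records, truth = truth)
}

#' Write a simulated cohort to disk as a loadable fixture
#'
#' @param sim a `chd_simulation` from [generate_cohort()].
#' @param directory output directory (created if needed).
#' @return named character vector of the three file paths (procedures CSV,
#'   life-status CSV, ground-truth JSON).
#' @export
write_fixture <- function(sim, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stopf("cannot create fixture directory: %s", directory)
    }
  }
  paths <- c(procedures = file.path(directory, "procedures.csv"),
             life = file.path(directory, "life_status.csv"),
             truth = file.path(directory, "ground_truth.json"))
  utils::write.csv(sim$procedures, paths[["procedures"]],
                   row.names = FALSE, na = "")
  utils::write.csv(sim$life, paths[["life"]], row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "columns",
                       digits = NA, na = "null")
  paths
}

#' @export
print.chd_simulation <- function(x, ...) {
  cat("<chd_simulation> seed", x$seed, ":",
      nrow(x$truth$patients), "patients,",
      nrow(x$procedures), "procedure records,",
      sum(x$truth$patients$corrupted), "corrupted\n")
  invisible(x)
}
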