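# Shared fixtures: all built in code at test time.

dict <- sentinelchd::default_concept_dictionary()
rules <- sentinelchd::load_ruleset()

# A minimal procedures CSV written to a temp file.
write_procedures_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  header <- paste("patient_id", "age_days", "procedure_codes",
                  "diagnosis_codes", "modality", "discharge_age_days",
                  "center_id", "residency", "born_in_window", sep = ",")
  writeLines(c(header, rows), path)
  path
}

proc_row <- function(pid, age, proc, diag, modality = "bypass_surgery",
                     discharge = "", center = "C01",
                     residency = "england_wales", born = "TRUE") {
  paste(pid, age, proc, diag, modality, discharge, center, residency, born,
        sep = ",")
}

# Build a patient history directly from vectors (records already in desired
# file order; ages may be unsorted to exercise the sorting contract).
make_history <- function(pid, ages, proc_concepts,
                         diag_concepts = "dx_hlhs",
                         modality = "bypass_surgery",
                         nchda_death = NA, ons_death = NA, ons_confirm = NA,
                         discharge = NA) {
  k <- length(ages)
  rec <- data.frame(
    patient_id = rep(pid, k),
    age_days = as.integer(ages),
    procedure_codes = rep("", k),
    diagnosis_codes = rep("", k),
    procedure_concepts = rep_len(proc_concepts, k),
    diagnosis_concepts = rep_len(diag_concepts, k),
    modality = rep_len(modality, k),
    discharge_age_days = rep_len(as.integer(discharge), k),
    center_id = "C01", residency = "england_wales",
    born_in_window = TRUE, discharge_error = FALSE,
    row = seq_len(k), stringsAsFactors = FALSE)
  ord <- order(rec$age_days, rec$row)
  rec <- rec[ord, , drop = FALSE]
  life <- data.frame(patient_id = pid,
                     nchda_death_age_days = as.integer(nchda_death),
                     ons_death_age_days = as.integer(ons_death),
                     ons_alive_confirm_age_days = as.integer(ons_confirm))
  list(patient_id = pid, records = rec, life_status = life)
}

# Single-diagnosis spec with overridable block fields, for targeted
# generator experiments.
one_block_spec <- function(dx, n = 2000, global = list(), ...) {
  bt <- sentinelchd:::default_block_table()[dx]
  bt[[dx]]$n <- n
  over <- list(...)
  for (f in names(over)) bt[[dx]][[f]] <- over[[f]]
  sentinelchd::cohort_spec(bt, global)
}

# Run the analysis pipeline on an in-memory simulation (no disk round trip).
analyze_sim <- function(sim) {
  recs <- sentinelchd:::as_procedure_records(sim$procedures, dict)
  cohort <- link_patients(recs, sim$life)
  dx <- assign_diagnoses(cohort, dict, rules)
  pw <- assign_pathways(cohort, dx, dict, rules)
  fl <- flag_patients(pw$assignments, ruleset = rules)
  la <- ascertain_life(cohort)
  eh <- build_event_histories(dx, pw, la, fl)
  list(cohort = cohort, diagnoses = dx, pathways = pw, flags = fl,
       life_asc = la, eh = eh)
}

# Independent brute-force oracles for the estimator tests ------------------

# Product-limit survival computed naively over the raw data.
brute_km <- function(time, status, t) {
  et <- sort(unique(time[status == 1]))
  s <- 1
  for (ti in et[et <= t]) {
    n_i <- sum(time >= ti)
    d_i <- sum(time == ti & status == 1)
    s <- s * (1 - d_i / n_i)
  }
  s
}

# Aalen-Johansen cumulative incidence computed naively.
brute_cif <- function(time, event, cause, t) {
  et <- sort(unique(time[event > 0]))
  s_minus <- 1
  f <- 0
  for (ti in et) {
    n_i <- sum(time >= ti)
    d_all <- sum(time == ti & event > 0)
    d_k <- sum(time == ti & event == cause)
    if (ti <= t) f <- f + s_minus * d_k / n_i
    s_minus <- s_minus * (1 - d_all / n_i)
  }
  f
}
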