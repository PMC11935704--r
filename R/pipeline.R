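# End-to-end orchestration: simulate or ingest, phenotype, classify
# pathways, flag quality, estimate, and emit an audit-style report bundle
# with stage-by-stage counts (a reproducible inclusion flow chart).

#' Build a pipeline run configuration
#'
#' Exactly one of `procedures_path`/`life_path` (ingest mode) or
#' `simulation_spec` (simulate mode) must be provided.
#'
#' @param procedures_path,life_path input CSV paths (ingest mode).
#' @param simulation_spec a [cohort_spec()] (simulate mode).
#' @param dictionary_path,ruleset_path optional paths overriding the bundled
#'   concept dictionary and ruleset.
#' @param report_ages report ages in days.
#' @param exclude_flagged_reint exclude quality-flagged patients from
#'   reintervention metrics.
#' @param seed integer seed (simulate mode and any randomness).
#' @param output_dir optional output directory for [write_report_bundle()].
#' @return list of class `run_config`.
#' @export
run_config <- function(procedures_path = NULL, life_path = NULL,
                       simulation_spec = NULL,
                       dictionary_path = NULL, ruleset_path = NULL,
                       report_ages = report_ages_default(),
                       exclude_flagged_reint = TRUE,
                       seed = 1L, output_dir = NULL) {
  ingest <- !is.null(procedures_path)
  simulate <- !is.null(simulation_spec)
  if (ingest == simulate) {
    stopf("run_config: provide exactly one of input paths or a simulation spec")
  }
  if (ingest && is.null(life_path)) stopf("run_config: life_path required")
  structure(list(procedures_path = procedures_path, life_path = life_path,
                 simulation_spec = simulation_spec,
                 dictionary_path = dictionary_path,
                 ruleset_path = ruleset_path,
                 report_ages = report_ages,
                 exclude_flagged_reint = exclude_flagged_reint,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: ingest (or simulate) -> link -> exclusions ->
#' phenotype -> pathway -> quality flags -> outcomes -> tables. Every stage
#' logs in/out counts, forming a reproducible inclusion flow chart. The run
#' is deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return list of class `report_bundle`: `flowchart`, `diagnoses`,
#'   `assignments`, `reinterventions`, `flags`, `event_histories`,
#'   `metrics`, `completion`, `scoping`, `manifest` (and `truth` in
#'   simulate mode).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dict <- if (is.null(config$dictionary_path)) default_concept_dictionary()
          else load_concept_dictionary(config$dictionary_path)
  rules <- load_ruleset(config$ruleset_path)

  stage <- "ingest"
  bundle <- tryCatch({
    truth <- NULL
    if (!is.null(config$simulation_spec)) {
      sim <- generate_cohort(config$simulation_spec, config$seed, dict)
      records <- as_procedure_records(sim$procedures, dict)
      life <- check_life_conflicts(sim$life)
      truth <- sim$truth
    } else {
      records <- read_procedure_table(config$procedures_path, dict)
      life <- read_life_status(config$life_path)
    }
    n_records <- nrow(records)

    stage <- "link"
    cohort <- link_patients(records, life)
    n_initial <- n_patients(cohort)

    stage <- "phenotype"
    diagnoses <- assign_diagnoses(cohort, dict, rules)

    stage <- "exclusions"
    excl <- apply_exclusions(cohort, diagnoses)
    keep_ids <- excl$patient_id[!excl$excluded]
    keep_rec <- cohort$procedures[cohort$procedures$patient_id %in% keep_ids, ,
                                  drop = FALSE]
    cohort_kept <- link_patients(keep_rec, cohort$life)
    diagnoses <- diagnoses[diagnoses$patient_id %in% keep_ids, , drop = FALSE]

    stage <- "pathway"
    pathways <- assign_pathways(cohort_kept, diagnoses, dict, rules)

    stage <- "quality_flags"
    first_age <- vapply(split(cohort_kept$procedures$age_days,
                              match(cohort_kept$procedures$patient_id,
                                    cohort_kept$patients)),
                        min, numeric(1))
    flags <- flag_patients(pathways$assignments,
                           first_proc_age = first_age[
                             as.character(seq_along(cohort_kept$patients))],
                           ruleset = rules)

    stage <- "outcomes"
    life_asc <- ascertain_life(cohort_kept)
    eh <- build_event_histories(diagnoses, pathways, life_asc, flags)

    stage <- "tables"
    metrics <- metrics_table(eh, config$report_ages,
                             config$exclude_flagged_reint)
    clean <- pathways$assignments[
      !flags$flagged[match(pathways$assignments$patient_id,
                           flags$patient_id)], , drop = FALSE]
    completion <- pathway_completion_summary(clean)
    scoping <- scoping_metrics(cohort_kept, diagnoses, life_asc)

    flowchart <- emit_flowchart_counts(list(
      n_records = n_records, n_initial = n_initial, exclusions = excl,
      diagnoses = diagnoses))

    manifest <- list(
      dictionary_version = dict$version,
      ruleset_version = rules$version,
      seed = config$seed,
      report_ages_days = config$report_ages,
      exclude_flagged_reint = config$exclude_flagged_reint,
      n_records = n_records, n_patients = n_initial,
      n_analyzed = length(keep_ids),
      n_flagged = sum(flags$flagged))

    structure(list(flowchart = flowchart, diagnoses = diagnoses,
                   assignments = pathways$assignments,
                   reinterventions = pathways$reinterventions,
                   flags = flags, event_histories = eh, metrics = metrics,
                   completion = completion, scoping = scoping,
                   manifest = manifest, truth = truth),
              class = "report_bundle")
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  bundle
}

#' Inclusion flow-chart counts
#'
#' Ordered rows: initial patient count, one row per exclusion reason, the
#' retained count, and the sentinel subset. Count conservation holds at
#' every stage: initial = retained + sum of exclusions.
#'
#' @param stage_logs list with `n_initial`, `exclusions` (from
#'   [apply_exclusions()]) and `diagnoses`.
#' @return data.frame with columns stage, n.
#' @export
emit_flowchart_counts <- function(stage_logs) {
  excl <- stage_logs$exclusions
  rows <- data.frame(stage = "initial_patients", n = stage_logs$n_initial,
                     stringsAsFactors = FALSE)
  for (why in EXCLUSION_REASONS) {
    rows <- rbind(rows, data.frame(
      stage = paste0("excluded_", why),
      n = sum(excl$reason == why, na.rm = TRUE)))
  }
  retained <- sum(!excl$excluded)
  dx <- stage_logs$diagnoses
  sentinel <- sum(dx$diagnosis[match(excl$patient_id[!excl$excluded],
                                     dx$patient_id)] %in% SENTINEL_DIAGNOSES)
  rbind(rows,
        data.frame(stage = "retained", n = retained),
        data.frame(stage = "sentinel_cohort", n = sentinel))
}

#' Write a report bundle to disk
#'
#' CSV tables plus a JSON manifest carrying versions, the seed and per-file
#' checksums for audit provenance. No wall-clock timestamps are written, so
#' regeneration from the same configuration and seed is byte-identical.
#'
#' @param bundle a `report_bundle`.
#' @param directory output directory.
#' @return named vector of written paths.
#' @export
write_report_bundle <- function(bundle, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  tables <- c("flowchart", "diagnoses", "assignments", "reinterventions",
              "flags", "event_histories", "metrics", "completion", "scoping")
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(directory, paste0(tb, ".csv"))
    utils::write.csv(bundle[[tb]], p, row.names = FALSE, na = "")
    paths[tb] <- p
  }
  manifest <- bundle$manifest
  manifest$checksums <- as.list(tools::md5sum(unname(paths)))
  names(manifest$checksums) <- basename(unname(paths))
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["manifest"] <- mp
  invisible(paths)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  print(x$flowchart, row.names = FALSE)
  invisible(x)
}
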