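#' Cohort specifications for the synthetic registry
#'
#' A cohort spec holds one block per diagnosis (cohort size, subgroup mix,
#' age/weight-at-first-procedure log-normal parameters, pathway template,
#' piecewise death/reintervention hazards) plus global settings (follow-up
#' horizon, loss to follow-up, corruption rate). Hazards are calibrated at
#' construction from survival and reintervention targets at ages 1/5/10 years
#' using the closed-form expressions for piecewise-constant hazards, so the
#' survival and cumulative incidence the generator implies are known exactly.
#'
#' @param blocks named list of per-diagnosis blocks (see
#'   [default_cohort_spec()] for the field set).
#' @param global list of global settings.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(blocks, global = list()) {
  g <- utils::modifyList(list(
    followup_years = c(0.4, 22.4),
    ltfu_rate = 0.02,
    corruption_rate = 0.01,
    n_centers = 12,
    residency_mix = c(england_wales = 1, other = 0, non_nhs = 0),
    death_source_mix = c(both = 0.6, ons_only = 0.3, nchda_only = 0.1),
    gap_sdlog = 0.45), global)
  blocks <- lapply(blocks, calibrate_block)
  spec <- structure(list(blocks = blocks, global = g), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

calibrate_block <- function(blk) {
  blk$death_hazard <- blk$death_hazard %||%
    calibrate_death_hazard(blk$surv_targets)
  comp <- blk$death_hazard + rep(blk$tx_rate %||% 0, 4)
  blk$reint_hazard <- blk$reint_hazard %||%
    calibrate_reint_hazard(blk$reint_targets, comp)
  blk
}

validate_cohort_spec <- function(spec) {
  if (!length(spec$blocks)) stopf("cohort spec: no diagnosis blocks")
  for (dx in names(spec$blocks)) {
    blk <- spec$blocks[[dx]]
    if (is.null(blk$n) || blk$n < 0) stopf("block %s: n must be >= 0", dx)
    mix <- blk$subgroup_mix
    if (abs(sum(mix) - 1) > 1e-9) {
      stopf("block %s: subgroup mix sums to %.12f, not 1", dx, sum(mix))
    }
    if (any(mix < 0)) stopf("block %s: negative subgroup probability", dx)
    for (field in c("death_hazard", "reint_hazard")) {
      if (any(blk[[field]] < 0)) stopf("block %s: negative %s", dx, field)
    }
    for (p in c("prematurity_rate", "comorbidity_rate", "sv_fraction",
                "prepathway_prob", "bv_stage1_prob", "bv_repair_prob")) {
      v <- blk[[p]] %||% 0
      if (v < 0 || v > 1) stopf("block %s: %s outside [0,1]", dx, p)
    }
  }
  for (p in c("ltfu_rate", "corruption_rate")) {
    v <- spec$global[[p]]
    if (v < 0 || v > 1) stopf("cohort spec: %s outside [0,1]", p)
  }
  invisible(spec)
}

# Default per-diagnosis calibration table the bundled generator emulates:
# cohort sizes, subgroup mixes, age/weight at first procedure (median and
# quartiles), prematurity/comorbidity rates, survival and reintervention
# incidence at 1/5/10 y, pathway template parameters.
default_block_table <- function() {
  list(
    HLHS = list(
      n = 1296, subgroup_mix = c(hlhs = 1),
      age_first = c(4, 3, 6), weight = c(3.1, 2.8, 3.5),
      prematurity_rate = 0.042, comorbidity_rate = 0.140,
      surv_targets = c(0.638, 0.591, 0.576),
      reint_targets = c(0.374, 0.487, 0.545),
      sv_fraction = 1, sv_attain = c(0.97, 0.75, 0.70),
      bv_stage1_prob = 0, bv_repair_prob = 0,
      prepathway_prob = 0.10, tx_rate = 0.004, reint_surgical_share = 0.5),
    FUH = list(
      n = 997,
      subgroup_mix = c(double_inlet_ventricle = 443, tricuspid_atresia = 554) / 997,
      age_first = c(18, 6, 69), weight = c(3.4, 3.0, 4.3),
      prematurity_rate = 0.078, comorbidity_rate = 0.145,
      surv_targets = c(0.904, 0.878, 0.867),
      reint_targets = c(0.279, 0.460, 0.573),
      sv_fraction = 1, sv_attain = c(0.93, 0.80, 0.78),
      bv_stage1_prob = 0, bv_repair_prob = 0,
      prepathway_prob = 0.12, tx_rate = 0.003, reint_surgical_share = 0.5),
    TGA = list(
      n = 3838,
      subgroup_mix = c(complex_with_PS = 447, complex_without_PS = 1283,
                       intact_septum = 2108) / 3838,
      age_first = c(5, 1, 13), weight = c(3.3, 3.0, 3.7),
      prematurity_rate = 0.041, comorbidity_rate = 0.052,
      surv_targets = c(0.944, 0.935, 0.931),
      reint_targets = c(0.132, 0.184, 0.209),
      sv_fraction = 0.024, sv_attain = c(0.92, 0.80, 0.72),
      bv_stage1_prob = 0.05, bv_repair_prob = 0.97,
      prepathway_prob = 0.55, tx_rate = 5e-4, reint_surgical_share = 0.45),
    PA = list(
      n = 1643,
      subgroup_mix = c(with_VSD = 1131, intact_septum = 512) / 1643,
      age_first = c(14, 5, 84), weight = c(3.3, 2.8, 4.3),
      prematurity_rate = 0.107, comorbidity_rate = 0.281,
      surv_targets = c(0.865, 0.821, 0.810),
      reint_targets = c(0.360, 0.593, 0.668),
      sv_fraction = 0.102, sv_attain = c(0.95, 0.78, 0.70),
      bv_stage1_prob = 0.45, bv_repair_prob = 0.85,
      prepathway_prob = 0.05, tx_rate = 5e-4, reint_surgical_share = 0.5),
    AVSD = list(
      n = 4358,
      subgroup_mix = c(tetralogy_AVSD = 215, unbalanced = 291,
                       partial = 1108, complete = 2744) / 4358,
      age_first = c(157, 94, 430), weight = c(5.3, 4.1, 8.5),
      prematurity_rate = 0.075, comorbidity_rate = 0.538,
      surv_targets = c(0.923, 0.892, 0.885),
      reint_targets = c(0.095, 0.176, 0.216),
      sv_fraction = 0.031, sv_attain = c(0.95, 0.80, 0.72),
      bv_stage1_prob = 0.08, bv_repair_prob = 0.96,
      prepathway_prob = 0.02, tx_rate = 3e-4, reint_surgical_share = 0.55),
    TOF = list(
      n = 4643,
      subgroup_mix = c(absent_pulm_valve = 185, DORV = 546,
                       standard = 3912) / 4643,
      age_first = c(193, 107, 306), weight = c(6.7, 5.0, 8.2),
      prematurity_rate = 0.088, comorbidity_rate = 0.223,
      surv_targets = c(0.973, 0.957, 0.951),
      reint_targets = c(0.088, 0.211, 0.266),
      sv_fraction = 0, sv_attain = c(0, 0, 0),
      bv_stage1_prob = 0.168, bv_repair_prob = 0.984,
      prepathway_prob = 0, tx_rate = 2e-4, reint_surgical_share = 0.5),
    AS = list(
      n = 1631,
      subgroup_mix = c(multilevel_LHO = 434, isolated = 1197) / 1631,
      age_first = c(112, 19, 1305), weight = c(5.9, 3.6, 15.7),
      prematurity_rate = 0.057, comorbidity_rate = 0.086,
      surv_targets = c(0.955, 0.947, 0.944),
      reint_targets = c(0.134, 0.219, 0.312),
      sv_fraction = 0, sv_attain = c(0, 0, 0),
      bv_stage1_prob = 0, bv_repair_prob = 0.97,
      prepathway_prob = 0, tx_rate = 2e-4, reint_surgical_share = 0.35),
    COARCT = list(
      n = 4338,
      subgroup_mix = c(with_VSD = 1333, isolated = 3005) / 4338,
      age_first = c(20, 8, 110), weight = c(3.6, 3.0, 5.5),
      prematurity_rate = 0.073, comorbidity_rate = 0.120,
      surv_targets = c(0.976, 0.969, 0.967),
      reint_targets = c(0.118, 0.168, 0.198),
      sv_fraction = 0, sv_attain = c(0, 0, 0),
      bv_stage1_prob = 0, bv_repair_prob = 0.98,
      prepathway_prob = 0, tx_rate = 1e-4, reint_surgical_share = 0.55),
    VSD = list(
      n = 6575,
      subgroup_mix = c(multiple = 426, isolated = 6149) / 6575,
      age_first = c(154, 94, 317), weight = c(5.3, 4.2, 7.6),
      prematurity_rate = 0.100, comorbidity_rate = 0.238,
      surv_targets = c(0.984, 0.973, 0.969),
      reint_targets = c(0.028, 0.053, 0.061),
      sv_fraction = 0, sv_attain = c(0, 0, 0),
      bv_stage1_prob = 0.03, bv_repair_prob = 0.98,
      prepathway_prob = 0, tx_rate = 1e-4, reint_surgical_share = 0.5)
  )
}

# Inter-stage gap defaults (median days); shared log-sd from the global spec.
GAP_MEDIANS <- c(pre = 6, s12 = 120, s23 = 1095, s1rep = 270)

#' Default calibrated cohort specification
#'
#' The bundled default emulates a national 22-year cohort: per-diagnosis
#' sizes, subgroup mixes, first-procedure age/weight distributions,
#' prematurity/comorbidity rates, and hazards whose implied survival and
#' reintervention incidence at 1/5/10 years match the calibration targets.
#'
#' @param n_patients optional named integer vector overriding block sizes,
#'   e.g. `c(HLHS = 2000)`; unnamed scalar rescales every block to that size.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_patients = NULL) {
  blocks <- default_block_table()
  if (!is.null(n_patients)) {
    if (is.null(names(n_patients)) && length(n_patients) == 1L) {
      n_patients <- stats::setNames(rep(n_patients, length(blocks)),
                                    names(blocks))
    }
    for (dx in names(n_patients)) {
      if (!dx %in% names(blocks)) stopf("unknown diagnosis block: %s", dx)
      blocks[[dx]]$n <- as.integer(n_patients[[dx]])
    }
  }
  cohort_spec(blocks)
}

#' Survival and reintervention incidence implied by a cohort spec
#'
#' Closed-form values under the spec's piecewise hazards; these are the
#' ground-truth quantities the downstream estimators should recover.
#'
#' @param spec a [cohort_spec()].
#' @param diagnosis diagnosis block name.
#' @param ages_years ages at which to evaluate.
#' @return numeric vector.
#' @export
implied_survival <- function(spec, diagnosis, ages_years = c(1, 5, 10)) {
  surv_pw(ages_years, spec$blocks[[diagnosis]]$death_hazard)
}

#' @rdname implied_survival
#' @export
implied_reint_cif <- function(spec, diagnosis, ages_years = c(1, 5, 10)) {
  blk <- spec$blocks[[diagnosis]]
  comp <- blk$death_hazard + rep(blk$tx_rate %||% 0, 4)
  cif_pw(ages_years, blk$reint_hazard, comp)
}

#' Read / write a cohort spec as a YAML document
#' @param path YAML path.
#' @export
load_cohort_spec <- function(path) {
  doc <- yaml::read_yaml(path)
  blocks <- lapply(doc$blocks, function(b) {
    for (f in c("subgroup_mix", "age_first", "weight", "surv_targets",
                "reint_targets", "sv_attain")) {
      if (!is.null(b[[f]])) b[[f]] <- unlist(b[[f]])
    }
    b
  })
  global <- doc$global %||% list()
  for (f in c("followup_years", "residency_mix", "death_source_mix")) {
    if (!is.null(global[[f]])) global[[f]] <- unlist(global[[f]])
  }
  cohort_spec(blocks, global)
}

#' @rdname load_cohort_spec
#' @param spec a [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  doc <- list(blocks = lapply(spec$blocks, function(b) {
    b$death_hazard <- NULL; b$reint_hazard <- NULL  # recalibrated on load
    lapply(b, function(x) if (is.numeric(x) && !is.null(names(x)))
      as.list(x) else x)
  }), global = lapply(spec$global, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", length(x$blocks), "diagnosis blocks, total n =",
      sum(vapply(x$blocks, function(b) b$n, numeric(1))), "\n")
  invisible(x)
}
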