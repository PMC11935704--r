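test_that("procedure roles look up by diagnosis", {
  expect_equal(classify_procedure_role(
    list(procedure_concepts = "proc_norwood"), "HLHS", dict), "stage1")
  expect_equal(classify_procedure_role(
    list(procedure_concepts = "proc_bas"), "TGA", dict), "prepathway")
  expect_equal(classify_procedure_role(
    list(procedure_concepts = "proc_tof_repair"), "TOF", dict), "repair")
  # no role for this diagnosis -> other
  expect_equal(classify_procedure_role(
    list(procedure_concepts = "proc_norwood"), "TOF", dict), "other")
})

test_that("repeat pathway procedures become reinterventions", {
  # staged single-ventricle history with a Glenn revision
  h <- make_history("p1", c(4, 150, 200),
                    c("proc_norwood", "proc_glenn", "proc_glenn"), "dx_hlhs")
  a <- assign_pathway(h, "HLHS", dict, rules)
  expect_equal(unname(a$slots[c("stage1", "stage2")]), c(4L, 150L))
  expect_true(is.na(a$slots[["stage3"]]))
  expect_equal(nrow(a$reinterventions), 1L)
  expect_equal(a$reinterventions$age_days, 200L)
  expect_equal(a$reinterventions$category, "surgical")
})

test_that("palliate-then-repair fills both slots with no reintervention", {
  h <- make_history("p1", c(30, 200), c("proc_bt_shunt", "proc_tof_repair"),
                    "dx_tof", modality = c("nonbypass_surgery", "bypass_surgery"))
  a <- assign_pathway(h, "TOF", dict, rules)
  expect_equal(unname(a$slots[c("stage1", "repair")]), c(30L, 200L))
  expect_equal(nrow(a$reinterventions), 0L)
  expect_equal(a$pathway_type, "biventricular")
})

test_that("post-repair catheter procedures are catheter reinterventions", {
  h <- make_history("p1", c(150, 400),
                    c("proc_vsd_closure", "proc_interventional_cath"),
                    "dx_vsd", modality = c("bypass_surgery", "catheter"))
  a <- assign_pathway(h, "VSD", dict, rules)
  expect_equal(unname(a$slots[["repair"]]), 150L)
  expect_equal(a$reinterventions$category, "catheter")
  expect_equal(a$reinterventions$age_days, 400L)
})

test_that("prepathway and transplant records are never reinterventions", {
  h <- make_history("p1", c(1, 2, 5, 900),
                    c("proc_bas", "proc_bas", "proc_arterial_switch",
                      "proc_transplant"),
                    "dx_tga",
                    modality = c("catheter", "catheter", "bypass_surgery",
                                 "bypass_surgery"))
  a <- assign_pathway(h, "TGA", dict, rules)
  expect_equal(nrow(a$reinterventions), 0L)
  expect_equal(a$transplant_age_days, 900L)
  expect_equal(unname(a$slots[["prepathway"]]), 1L)
})

test_that("diagnostic electrophysiology before the pathway is not a reintervention", {
  h <- make_history("p1", c(50, 100, 400),
                    c("proc_ep_ablation", "proc_tof_repair",
                      "proc_ep_ablation"),
                    "dx_tof",
                    modality = c("electrophysiology", "bypass_surgery",
                                 "electrophysiology"))
  a <- assign_pathway(h, "TOF", dict, rules)
  # before the first pathway procedure: not counted; after: counted
  expect_equal(nrow(a$reinterventions), 1L)
  expect_equal(a$reinterventions$age_days, 400L)
})

test_that("same-day slot ties resolve by file order", {
  h <- make_history("p1", c(100, 100),
                    c("proc_glenn", "proc_glenn"), "dx_hlhs")
  a <- assign_pathway(h, "HLHS", dict, rules)
  expect_equal(unname(a$slots[["stage2"]]), 100L)
  expect_equal(nrow(a$reinterventions), 1L)
})

test_that("stage records arriving after a later stage become reinterventions", {
  # stage 1 coded after the Glenn: slot ages must stay monotone
  h <- make_history("p1", c(100, 300), c("proc_glenn", "proc_norwood"),
                    "dx_hlhs")
  a <- assign_pathway(h, "HLHS", dict, rules)
  expect_true(is.na(a$slots[["stage1"]]))
  expect_equal(unname(a$slots[["stage2"]]), 100L)
  expect_equal(a$reinterventions$age_days, 300L)
})

test_that("pathway type classification covers all three cases", {
  staged <- list(slots = c(prepathway = NA, stage1 = 4, stage2 = 150,
                           stage3 = 1100, repair = NA))
  expect_equal(determine_pathway_type(staged), "single_ventricle")
  repaired <- list(slots = c(prepathway = NA, stage1 = NA, stage2 = NA,
                             stage3 = NA, repair = 200))
  expect_equal(determine_pathway_type(repaired), "biventricular")
  both <- list(slots = c(prepathway = NA, stage1 = 4, stage2 = 150,
                         stage3 = NA, repair = 200))
  expect_equal(determine_pathway_type(both), "indeterminate")
  neither <- list(slots = c(prepathway = 1, stage1 = NA, stage2 = NA,
                            stage3 = NA, repair = NA))
  expect_equal(determine_pathway_type(neither), "indeterminate")
})

test_that("every interventional record is counted exactly once (partition)", {
  spec <- default_cohort_spec(80)
  spec$global$corruption_rate <- 0
  sim <- generate_cohort(spec, 41)
  res <- analyze_sim(sim)
  a <- res$pathways$assignments
  n_slots <- sum(!is.na(a$stage1_age)) + sum(!is.na(a$stage2_age)) +
    sum(!is.na(a$stage3_age)) + sum(!is.na(a$repair_age))
  n_reints <- nrow(res$pathways$reinterventions)
  rec <- res$cohort$procedures
  n_prepath <- sum(rec$procedure_concepts == "proc_bas")
  n_tx <- sum(rec$procedure_concepts == "proc_transplant")
  expect_equal(n_slots + n_reints + n_prepath + n_tx, nrow(rec))
})

test_that("pathway assignment is idempotent and matches ground truth exactly", {
  spec <- default_cohort_spec(100)
  spec$global$corruption_rate <- 0
  sim <- generate_cohort(spec, 43)
  res <- analyze_sim(sim)
  again <- assign_pathways(res$cohort, res$diagnoses, dict, rules)
  expect_identical(res$pathways, again)
  tr <- sim$truth$reinterventions
  pr <- res$pathways$reinterventions
  expect_setequal(paste(tr$patient_id, tr$age_days, tr$category),
                  paste(pr$patient_id, pr$age_days, pr$category))
  tp <- sim$truth$patients
  m <- match(tp$patient_id, res$pathways$assignments$patient_id)
  for (s in c("prepathway_age", "stage1_age", "stage2_age", "stage3_age",
              "repair_age")) {
    expect_identical(res$pathways$assignments[[s]][m], tp[[s]],
                     label = s)
  }
})

test_that("completion summary reports counts and one-decimal percentages", {
  a <- data.frame(diagnosis = "HLHS",
                  prepathway_age = NA_integer_,
                  stage1_age = c(rep(4L, 3), NA),
                  stage2_age = c(150L, 150L, NA, NA),
                  stage3_age = rep(NA_integer_, 4),
                  repair_age = rep(NA_integer_, 4))
  s <- pathway_completion_summary(a)
  expect_equal(s$pct[s$slot == "stage1"], 75.0)
  expect_equal(s$pct[s$slot == "stage2"], 50.0)
  expect_equal(s$pct[s$slot == "repair"], 0.0)
})
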