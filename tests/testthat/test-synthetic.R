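test_that("an all-zero spec yields empty outputs", {
  spec <- default_cohort_spec(0)
  sim <- generate_cohort(spec, 1)
  expect_equal(nrow(sim$procedures), 0L)
  expect_equal(nrow(sim$life), 0L)
  expect_equal(nrow(sim$truth$patients), 0L)
})

test_that("generation is deterministic given the seed", {
  spec <- default_cohort_spec(c(HLHS = 150, FUH = 0, TGA = 150, PA = 0,
                                AVSD = 0, TOF = 0, AS = 0, COARCT = 0,
                                VSD = 150))
  s1 <- generate_cohort(spec, 99)
  s2 <- generate_cohort(spec, 99)
  expect_identical(s1$procedures, s2$procedures)
  expect_identical(s1$life, s2$life)
  expect_identical(s1$truth, s2$truth)
  # and fixture files are byte-stable
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_fixture(s1, d1); p2 <- write_fixture(s2, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # different seed changes the draw
  s3 <- generate_cohort(spec, 100)
  expect_false(identical(s1$procedures, s3$procedures))
})

test_that("per-block sub-streams isolate blocks from spec edits", {
  spec_a <- default_cohort_spec(c(HLHS = 100, FUH = 0, TGA = 100, PA = 0,
                                  AVSD = 0, TOF = 0, AS = 0, COARCT = 0,
                                  VSD = 0))
  spec_b <- default_cohort_spec(c(HLHS = 100, FUH = 0, TGA = 300, PA = 0,
                                  AVSD = 0, TOF = 0, AS = 0, COARCT = 0,
                                  VSD = 0))
  a <- generate_cohort(spec_a, 7)
  b <- generate_cohort(spec_b, 7)
  hl_a <- a$procedures[grepl("^HLHS", a$procedures$patient_id), ]
  hl_b <- b$procedures[grepl("^HLHS", b$procedures$patient_id), ]
  rownames(hl_a) <- rownames(hl_b) <- NULL
  expect_identical(hl_a, hl_b)
})

test_that("stage attainment fractions match the template probabilities", {
  # Death, transplant and reintervention hazards are zeroed and the
  # follow-up horizon pushed past every stage age, so attainment is pure
  # Bernoulli; 3-SE binomial bands.
  p <- c(0.97, 0.65, 0.44)
  spec <- one_block_spec(
    "HLHS", n = 2000,
    global = list(ltfu_rate = 0, corruption_rate = 0,
                  followup_years = c(30, 30)),
    sv_attain = p,
    death_hazard = rep(0, 4), reint_hazard = rep(0, 4), tx_rate = 0,
    surv_targets = c(1, 1, 1), reint_targets = c(0, 0, 0))
  sim <- generate_cohort(spec, 12)
  tp <- sim$truth$patients
  obs <- c(mean(!is.na(tp$stage1_age)),
           mean(!is.na(tp$stage2_age)) / mean(!is.na(tp$stage1_age)),
           mean(!is.na(tp$stage3_age)) / mean(!is.na(tp$stage2_age)))
  se <- sqrt(p * (1 - p) / 2000)
  expect_true(all(abs(obs - p) < 3 * se + 0.01))
})

test_that("corruption rate 0 is the identity and rate 1 corrupts everyone", {
  spec <- one_block_spec("HLHS", n = 10,
                         global = list(corruption_rate = 0, ltfu_rate = 0))
  sim <- generate_cohort(spec, 3)
  out <- inject_data_issues(sim$procedures, sim$truth, 0, 5, dict)
  expect_identical(out$records, sim$procedures)
  out1 <- inject_data_issues(sim$procedures, sim$truth, 1, 5, dict)
  expect_true(all(out1$truth$patients$corrupted))
})

test_that("corrupted patient count follows the binomial at rate 0.01", {
  spec <- default_cohort_spec(c(HLHS = 2000, FUH = 0, TGA = 2000, PA = 0,
                                AVSD = 0, TOF = 2000, AS = 0, COARCT = 0,
                                VSD = 2000))
  sim <- generate_cohort(spec, 21)
  n <- nrow(sim$truth$patients)
  k <- sum(sim$truth$patients$corrupted)
  expect_lt(abs(k - 0.01 * n), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("zero death hazard gives survival identically 1 downstream", {
  spec <- one_block_spec(
    "TOF", n = 400, global = list(ltfu_rate = 0, corruption_rate = 0),
    death_hazard = rep(0, 4), tx_rate = 0, surv_targets = c(1, 1, 1))
  res <- analyze_sim(generate_cohort(spec, 8))
  km <- km_survival(res$eh$surv_time, res$eh$surv_event)
  expect_equal(km$report$surv, c(1, 1, 1))
  expect_equal(km$n_events, 0L)
})

test_that("zero reintervention hazard gives cumulative incidence 0 downstream", {
  spec <- one_block_spec(
    "VSD", n = 400, global = list(ltfu_rate = 0, corruption_rate = 0),
    reint_hazard = rep(0, 4), reint_targets = c(0, 0, 0))
  res <- analyze_sim(generate_cohort(spec, 9))
  cf <- cif_competing(res$eh$time_any, res$eh$event_any)
  expect_equal(cif_at(cf, report_ages_default()), c(0, 0, 0))
})

test_that("fixtures round-trip through the registry loaders", {
  spec <- default_cohort_spec(c(HLHS = 25, FUH = 0, TGA = 25, PA = 0,
                                AVSD = 0, TOF = 0, AS = 0, COARCT = 0,
                                VSD = 0))
  sim <- generate_cohort(spec, 4)
  d <- tempfile()
  paths <- write_fixture(sim, d)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  rec <- read_procedure_table(paths[["procedures"]], dict)
  expect_equal(nrow(rec), nrow(sim$procedures))
  expect_equal(rec$age_days, sim$procedures$age_days)
  life <- read_life_status(paths[["life"]])
  expect_equal(nrow(life), nrow(sim$life))
  # empty cohort writes headers-only files that still load
  sim0 <- generate_cohort(default_cohort_spec(0), 4)
  d0 <- tempfile()
  p0 <- write_fixture(sim0, d0)
  expect_equal(nrow(read_procedure_table(p0[["procedures"]], dict)), 0L)
  expect_equal(nrow(read_life_status(p0[["life"]])), 0L)
})

test_that("hazard calibration reproduces its targets in closed form", {
  blk <- sentinelchd:::default_block_table()$PA
  spec <- default_cohort_spec()
  expect_equal(implied_survival(spec, "PA"), blk$surv_targets,
               tolerance = 1e-10)
  expect_equal(implied_reint_cif(spec, "PA"), blk$reint_targets,
               tolerance = 1e-8)
})

test_that("invalid specs fail validation before sampling", {
  bt <- sentinelchd:::default_block_table()["HLHS"]
  bt$HLHS$subgroup_mix <- c(hlhs = 0.5)
  expect_error(cohort_spec(bt), "sums to")
  bt2 <- sentinelchd:::default_block_table()["HLHS"]
  bt2$HLHS$n <- -5
  expect_error(cohort_spec(bt2), "n must be")
})

test_that("cohort specs round-trip through YAML", {
  spec <- default_cohort_spec(c(HLHS = 50, FUH = 0, TGA = 0, PA = 0,
                                AVSD = 0, TOF = 0, AS = 0, COARCT = 0,
                                VSD = 50))
  f <- tempfile(fileext = ".yaml")
  write_cohort_spec(spec, f)
  spec2 <- load_cohort_spec(f)
  expect_equal(spec2$blocks$HLHS$n, 50)
  expect_equal(spec2$blocks$HLHS$death_hazard, spec$blocks$HLHS$death_hazard,
               tolerance = 1e-9)
  expect_identical(generate_cohort(spec, 2)$procedures,
                   generate_cohort(spec2, 2)$procedures)
})
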