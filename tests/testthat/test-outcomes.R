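test_that("life-status ascertainment follows the source precedence", {
  # audit death age wins over the mortality register
  h <- make_history("p1", 10, "proc_norwood", "dx_hlhs",
                    nchda_death = 180, ons_death = 181)
  out <- ascertain_life_status(h)
  expect_equal(out$terminal_kind, "death")
  expect_equal(out$terminal_age_days, 180)
  expect_equal(out$source, "nchda")
  # register death when the audit has none
  h2 <- make_history("p2", 10, "proc_norwood", "dx_hlhs", ons_death = 240)
  expect_equal(ascertain_life_status(h2)$source, "ons")
  # alive-confirmation censors
  h3 <- make_history("p3", 10, "proc_norwood", "dx_hlhs", ons_confirm = 4000)
  out3 <- ascertain_life_status(h3)
  expect_equal(out3$terminal_kind, "censor")
  expect_equal(out3$terminal_age_days, 4000)
  expect_false(out3$ltfu)
  # no register row: lost to follow-up, censored at last discharge
  h4 <- make_history("p4", 10, "proc_norwood", "dx_hlhs", discharge = 90)
  out4 <- ascertain_life_status(h4)
  expect_equal(out4$terminal_kind, "censor")
  expect_equal(out4$terminal_age_days, 90)
  expect_true(out4$ltfu)
  expect_equal(out4$source, "discharge")
})

test_that("product-limit estimate matches hand arithmetic", {
  # deaths at 1 and 2 years, censored at 3 and 4: S(2y) = (3/4)(2/3) = 1/2
  fit <- km_survival(years_to_days(1:4), c(1, 1, 0, 0),
                     report_ages = years_to_days(2))
  expect_equal(fit$report$surv, 0.5, tolerance = 1e-12)
  # no deaths: S identically 1, degenerate CI handled as [., 1]
  fit2 <- km_survival(years_to_days(1:4), rep(0, 4))
  expect_equal(fit2$report$surv, c(1, 1, 1))
  expect_equal(fit2$report$upper, c(1, 1, 1))
})

test_that("estimates and log(-log) intervals agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(101)
  for (rep in 1:3) {
    t <- rexp(300, 0.08)
    c <- runif(300, 0, 18)
    time <- pmin(t, c); status <- as.integer(t <= c)
    ages <- c(2, 5, 9)
    fit <- km_survival(time, status, report_ages = ages)
    sf <- summary(survival::survfit(
      survival::Surv(time, status) ~ 1, conf.type = "log-log"), times = ages)
    expect_equal(fit$report$surv, sf$surv, tolerance = 1e-9)
    expect_equal(fit$report$lower, sf$lower, tolerance = 1e-9)
    expect_equal(fit$report$upper, sf$upper, tolerance = 1e-9)
  }
})

test_that("Aalen-Johansen estimate matches hand arithmetic", {
  # reintervention at 1 y, death at 2 y, censored at 5 y
  fit <- cif_competing(years_to_days(c(1, 2, 5)), c(1L, 2L, 0L),
                       report_ages = years_to_days(5))
  expect_equal(fit$report$cif, c(1 / 3, 1 / 3), tolerance = 1e-12)
  st <- fit$steps
  expect_equal(st$surv + st$cif_reintervention + st$cif_death_or_transplant,
               rep(1, nrow(st)), tolerance = 1e-12)
})

test_that("competing-risks estimates agree with cmprsk", {
  skip_if_not_installed("cmprsk")
  set.seed(202)
  tt <- round(rexp(400, 0.2), 3)
  ev <- sample(0:2, 400, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  ages <- c(1, 3, 6)
  fit <- cif_competing(tt, ev, report_ages = ages)
  est <- cmprsk::timepoints(cmprsk::cuminc(tt, ev, cencode = 0), ages)
  expect_equal(cif_at(fit, ages, "reintervention"),
               unname(est$est["1 1", ]), tolerance = 1e-9)
  expect_equal(cif_at(fit, ages, "death_or_transplant"),
               unname(est$est["1 2", ]), tolerance = 1e-9)
  # delta-method variance close to the counting-process variance
  v <- vapply(ages, function(a) sentinelchd:::cif_variance_at(fit, 1, a),
              numeric(1))
  expect_equal(v, unname(est$var["1 1", ]), tolerance = 0.05)
})

test_that("reduction identities hold", {
  set.seed(303)
  for (rep in 1:5) {
    n <- 120
    t <- round(rexp(n, 0.3), 2)
    # no censoring: product-limit equals the empirical survival exactly
    fit <- km_survival(t, rep(1, n))
    grid <- sort(unique(t))
    expect_equal(km_at(fit, grid), vapply(grid, function(g) mean(t > g),
                                          numeric(1)), tolerance = 1e-12)
    # single cause: CIF = 1 - KM of that cause
    c2 <- runif(n, 0, 5)
    time <- pmin(t, c2); status <- as.integer(t <= c2)
    cf <- cif_competing(time, status, causes = "reintervention",
                        report_ages = grid)
    km <- km_survival(time, status, report_ages = grid)
    expect_equal(cif_at(cf, grid), 1 - km_at(km, grid), tolerance = 1e-12)
  }
})

test_that("CIF additivity holds at every step", {
  set.seed(404)
  tt <- round(rexp(500, 0.25), 2)
  ev <- sample(0:2, 500, replace = TRUE)
  fit <- cif_competing(tt, ev)
  st <- fit$steps
  expect_lt(max(abs(st$surv + st$cif_reintervention +
                      st$cif_death_or_transplant - 1)), 1e-9)
})

test_that("adding a death cannot increase later survival", {
  set.seed(505)
  t <- rexp(100, 0.1); c <- runif(100, 0, 12)
  time <- pmin(t, c); status <- as.integer(t <= c)
  base <- km_survival(time, status)
  aug <- km_survival(c(time, 4), c(status, 1))
  grid <- seq(4, 20, by = 0.5)
  expect_true(all(km_at(aug, grid) <= km_at(base, grid) + 1e-12))
})

test_that("ties process deaths before censorings", {
  # censored subject at the death time stays in the risk set
  fit <- km_survival(c(5, 5, 10), c(1, 0, 0), report_ages = 5)
  expect_equal(fit$steps$n_risk, 3)
  expect_equal(fit$report$surv, 2 / 3, tolerance = 1e-12)
})

test_that("a reintervention after recorded death is a data-integrity error", {
  spec <- one_block_spec("TOF", n = 300,
                         global = list(corruption_rate = 0, ltfu_rate = 0))
  sim <- generate_cohort(spec, 61)
  res <- analyze_sim(sim)
  # forge a reintervention one year after a death
  dead <- res$life_asc[res$life_asc$terminal_kind == "death", ]
  expect_gt(nrow(dead), 0)
  pw <- res$pathways
  pw$reinterventions <- rbind(pw$reinterventions, data.frame(
    patient_id = dead$patient_id[1], record_row = 0L,
    age_days = dead$terminal_age_days[1] + 365, modality = "catheter",
    category = "catheter"))
  expect_error(
    build_event_histories(res$diagnoses, pw, res$life_asc, res$flags),
    dead$patient_id[1], fixed = TRUE)
})

test_that("metric tables match independently scripted per-group estimates", {
  skip_if_not_installed("survival")
  spec <- default_cohort_spec(c(HLHS = 250, FUH = 0, TGA = 0, PA = 250,
                                AVSD = 0, TOF = 250, AS = 0, COARCT = 0,
                                VSD = 0))
  res <- analyze_sim(generate_cohort(spec, 71))
  tab <- metrics_table(res$eh)
  expect_equal(sort(unique(tab$diagnosis)), c("HLHS", "PA", "TOF"))
  # structural: one diagnosis row plus one per observed subgroup
  n_sub <- length(unique(paste(res$eh$diagnosis, res$eh$subgroup)))
  expect_equal(nrow(tab), 3 + n_sub)
  for (dx in c("HLHS", "PA", "TOF")) {
    sub <- res$eh[res$eh$diagnosis == dx, ]
    sf <- summary(survival::survfit(
      survival::Surv(surv_time, surv_event) ~ 1, data = sub,
      conf.type = "log-log"), times = report_ages_default())
    row <- tab[tab$level == "diagnosis" & tab$diagnosis == dx, ]
    expect_equal(unlist(row[sprintf("surv_%gy", c(1, 5, 10))],
                        use.names = FALSE), sf$surv, tolerance = 1e-9)
    # reintervention estimate equals the brute-force oracle on the
    # flag-excluded subset
    subr <- sub[!sub$flagged, ]
    for (age in report_ages_default()) {
      expect_equal(
        row[[sprintf("reint_any_%gy", age / 365.25)]],
        brute_cif(subr$time_any, subr$event_any, 1, age), tolerance = 1e-9)
    }
  }
})

test_that("scoping metrics count infancy, 3+ procedures, and deaths under 5", {
  path <- write_procedures_csv(c(
    proc_row("A", 100, "120901", "010601"),
    proc_row("B", 400, "120901", "010601"),
    proc_row("B", 500, "130101", "010601", "catheter"),
    proc_row("C", 50, "120901", "010601"),
    proc_row("C", 60, "130101", "010601", "catheter"),
    proc_row("C", 70, "130201", "010601", "nonbypass_surgery")))
  life <- data.frame(patient_id = c("A", "B", "C"),
                     nchda_death_age_days = c(NA, NA, 400L),
                     ons_death_age_days = NA_integer_,
                     ons_alive_confirm_age_days = c(4000L, 4000L, NA))
  cohort <- link_patients(read_procedure_table(path, dict), life)
  dx <- assign_diagnoses(cohort, dict, rules)
  sm <- scoping_metrics(cohort, dx, ascertain_life(cohort))
  expect_equal(sm$n, 3L)
  expect_equal(sm$pct_infancy, 66.7)   # A and C before 1 y, B not
  expect_equal(sm$pct_3plus, 33.3)     # only C has >= 3 procedures
  expect_equal(sm$pct_died_lt5y, 33.3) # only C died before 5 y
})
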