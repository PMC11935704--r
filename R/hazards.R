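# Piecewise-constant hazard machinery on the age segments
# [0,1), [1,5), [5,10), [10,Inf) years. Chosen so closed-form survival and
# competing-risks cumulative incidence at the report ages 1/5/10 y are
# available for calibrating the synthetic registry.

HAZARD_BREAKS_YEARS <- c(0, 1, 5, 10)
HAZARD_SEG_LENGTHS <- c(1, 4, 5, Inf)

# Cumulative hazard at t (years) for per-year segment rates (length 4).
cum_hazard_pw <- function(t, rates) {
  stopifnot(length(rates) == 4L)
  seg <- findInterval(t, HAZARD_BREAKS_YEARS)
  seg[seg < 1L] <- 1L
  Hb <- cumsum(c(0, rates[1:3] * HAZARD_SEG_LENGTHS[1:3]))
  Hb[seg] + rates[seg] * (t - HAZARD_BREAKS_YEARS[seg])
}

# Survival function S(t) = exp(-H(t)).
surv_pw <- function(t, rates) exp(-cum_hazard_pw(t, rates))

# Sample n event times (years) by inverting the cumulative hazard.
# Zero total hazard yields Inf.
sample_pw_exp <- function(n, rates) {
  stopifnot(length(rates) == 4L, all(rates >= 0))
  e <- stats::rexp(n)
  Hb <- cumsum(c(0, rates[1:3] * HAZARD_SEG_LENGTHS[1:3]))
  seg <- findInterval(e, Hb)  # 1..4 (e >= 0 = Hb[1])
  HAZARD_BREAKS_YEARS[seg] + (e - Hb[seg]) / rates[seg]
}

# Death hazard solved in closed form from survival targets at 1/5/10 y.
# The open-ended segment reuses the 5-10 y rate.
calibrate_death_hazard <- function(surv_targets) {
  stopifnot(length(surv_targets) == 3L,
            all(surv_targets > 0), all(surv_targets <= 1),
            !is.unsorted(rev(surv_targets)))
  s <- surv_targets
  r <- c(-log(s[1]), log(s[1] / s[2]) / 4, log(s[2] / s[3]) / 5)
  r <- pmax(r, 0)
  c(r, r[3])
}

# Closed-form cause-specific cumulative incidence at times t (years) when the
# event of interest and the competing event have independent piecewise
# hazards: on each segment with rates (lambda, mu),
#   F(t) = F0 + lambda/(lambda+mu) * S0 * (1 - exp(-(lambda+mu) * dt)).
cif_pw <- function(t, event_rates, comp_rates) {
  vapply(t, function(tt) {
    F0 <- 0; S0 <- 1
    for (k in 1:4) {
      lo <- HAZARD_BREAKS_YEARS[k]
      hi <- if (k < 4) HAZARD_BREAKS_YEARS[k + 1] else Inf
      if (tt <= lo) break
      dt <- min(tt, hi) - lo
      tot <- event_rates[k] + comp_rates[k]
      if (tot > 0) {
        drop <- S0 * (1 - exp(-tot * dt))
        F0 <- F0 + event_rates[k] / tot * drop
        S0 <- S0 - drop
      }
    }
    F0
  }, numeric(1))
}

# Solve the event hazard segment by segment so the closed-form competing-risks
# CIF hits the targets at 1/5/10 y given the competing hazard.
calibrate_reint_hazard <- function(cif_targets, comp_rates) {
  stopifnot(length(cif_targets) == 3L, !is.unsorted(cif_targets),
            all(cif_targets >= 0), all(cif_targets < 1))
  rates <- numeric(4)
  F0 <- 0; S0 <- 1
  seg_len <- c(1, 4, 5)
  for (k in 1:3) {
    target <- cif_targets[k]
    mu <- comp_rates[k]
    L <- seg_len[k]
    if (target <= F0 + 1e-12) {
      lam <- 0
    } else {
      if (target >= F0 + S0 * 0.999999) {
        stopf("infeasible reintervention target %.4f at segment %d", target, k)
      }
      f <- function(lam) {
        tot <- lam + mu
        F0 + lam / tot * S0 * (1 - exp(-tot * L)) - target
      }
      lam <- stats::uniroot(f, c(1e-12, 200), tol = 1e-12)$root
    }
    rates[k] <- lam
    tot <- lam + mu
    if (tot > 0) {
      drop <- S0 * (1 - exp(-tot * L))
      F0 <- F0 + lam / tot * drop
      S0 <- S0 - drop
    }
  }
  rates[4] <- rates[3]
  rates
}
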