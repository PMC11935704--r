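# Survival and competing-risks estimators.
#
# Kaplan-Meier product-limit with Greenwood variance and log(-log) 95% CIs;
# Aalen-Johansen cumulative incidence with delta-method variance and
# complementary log-log CIs. Deaths are processed before censorings at tied
# times (the standard risk-set convention: a patient censored at t is still
# at risk for an event at t).

#' Kaplan-Meier product-limit survival estimate
#'
#' @param time follow-up times (days on the age scale; time origin is birth).
#' @param status 1 = event (death), 0 = censored.
#' @param report_ages ages (same unit as `time`) at which to report the
#'   estimate with its confidence interval.
#' @param conf_level confidence level for the log(-log)-transformed Greenwood
#'   interval.
#' @return object of class `km_fit`: list with `steps` (time, n_risk,
#'   n_event, n_censor, surv, var_cll), `report` (age, surv, lower, upper),
#'   `n`, `n_events`.
#' @export
km_survival <- function(time, status, report_ages = report_ages_default(),
                        conf_level = 0.95) {
  stopifnot(length(time) == length(status), length(time) >= 1,
            all(status %in% c(0, 1)))
  et <- sort(unique(time[status == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & status == 1), numeric(1))
  n_censor <- vapply(et, function(t) sum(time == t & status == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood variance on the cumulative-hazard (log) scale; the term is 0
  # when the risk set is exhausted (n = d).
  incr <- ifelse(n_risk > n_event,
                 n_event / (n_risk * (n_risk - n_event)), 0)
  var_cll <- cumsum(incr)
  steps <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, surv = surv, var_cll = var_cll)
  fit <- structure(list(steps = steps, n = length(time),
                        n_events = sum(status == 1),
                        conf_level = conf_level),
                   class = "km_fit")
  fit$report <- km_report(fit, report_ages)
  fit
}

# Step-function evaluation: value at the largest step time <= t.
step_at <- function(step_times, values, t, init) {
  idx <- findInterval(t, step_times)
  out <- rep(init, length(t))
  out[idx > 0] <- values[idx[idx > 0]]
  out
}

km_report <- function(fit, ages) {
  z <- stats::qnorm(1 - (1 - fit$conf_level) / 2)
  s <- step_at(fit$steps$time, fit$steps$surv, ages, 1)
  v <- step_at(fit$steps$time, fit$steps$var_cll, ages, 0)
  lower <- upper <- rep(NA_real_, length(ages))
  inner <- s > 0 & s < 1
  # log(-log S) transform keeps the interval inside [0, 1].
  se_cll <- sqrt(v[inner]) / abs(log(s[inner]))
  lower[inner] <- s[inner]^exp(z * se_cll)
  upper[inner] <- s[inner]^exp(-z * se_cll)
  lower[s == 0] <- 0
  upper[s == 0] <- 0
  upper[s == 1] <- 1  # degenerate: no events yet; lower reported absent
  data.frame(age = ages, surv = s, lower = lower, upper = upper)
}

#' Evaluate a Kaplan-Meier fit at arbitrary ages
#' @param fit a `km_fit`.
#' @param ages ages at which to evaluate S(t).
#' @export
km_at <- function(fit, ages) step_at(fit$steps$time, fit$steps$surv, ages, 1)

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit>", x$n, "subjects,", x$n_events, "events\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' First-event-per-patient semantics: `event` gives the cause of the first
#' event (0 = censored). F_k(t) = sum over event times t_i <= t of
#' S(t_i-) d_ki / n_i, with S the all-cause event-free Kaplan-Meier.
#' Variances use the standard delta-method estimator; confidence intervals
#' are on the log(-log F) scale.
#'
#' @param time follow-up time to first event or censoring.
#' @param event integer cause: 0 censored, 1..K cause of first event.
#' @param causes character labels for causes 1..K.
#' @param report_ages report ages.
#' @param conf_level confidence level.
#' @return object of class `cif_fit`: `steps` (time, n_risk, per-cause
#'   events, per-cause F and variance, event-free surv), `report` (cause,
#'   age, cif, lower, upper), `n`.
#' @export
cif_competing <- function(time, event,
                          causes = c("reintervention", "death_or_transplant"),
                          report_ages = report_ages_default(),
                          conf_level = 0.95) {
  K <- length(causes)
  stopifnot(length(time) == length(event), all(event %in% 0:K))
  et <- sort(unique(time[event > 0]))
  nt <- length(et)
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  d_all <- vapply(et, function(t) sum(time == t & event > 0), numeric(1))
  d_k <- vapply(seq_len(K), function(k) {
    vapply(et, function(t) sum(time == t & event == k), numeric(1))
  }, numeric(nt))
  d_k <- matrix(d_k, nrow = nt, ncol = K)

  surv <- cumprod(1 - d_all / n_risk)          # all-cause event-free KM
  surv_minus <- c(1, surv[-length(surv)])      # S(t_i -)
  Fk <- apply(d_k, 2, function(d) cumsum(surv_minus * d / n_risk))
  Fk <- matrix(Fk, nrow = nt, ncol = K)

  steps <- data.frame(time = et, n_risk = n_risk, n_event = d_all,
                      surv = surv)
  for (k in seq_len(K)) {
    steps[[paste0("d_", causes[k])]] <- d_k[, k]
    steps[[paste0("cif_", causes[k])]] <- Fk[, k]
  }

  fit <- structure(list(steps = steps, causes = causes, n = length(time),
                        conf_level = conf_level,
                        d_k = d_k, Fk = Fk, surv_minus = surv_minus),
                   class = "cif_fit")
  fit$report <- cif_report(fit, report_ages)
  fit
}

# Delta-method variance of F_k(t) (Marubini-Valsecchi form).
cif_variance_at <- function(fit, k, t) {
  st <- fit$steps
  idx <- which(st$time <= t)
  if (!length(idx)) return(0)
  Ft <- fit$Fk[max(idx), k]
  Fi <- fit$Fk[idx, k]
  Si <- fit$surv_minus[idx]
  ni <- st$n_risk[idx]
  di <- st$n_event[idx]
  dki <- fit$d_k[idx, k]
  t1 <- sum(ifelse(ni > di, (Ft - Fi)^2 * di / (ni * (ni - di)), 0))
  t2 <- sum(Si^2 * ((ni - dki) / ni) * dki / ni^2)
  t3 <- sum((Ft - Fi) * Si * dki / ni^2)
  max(t1 + t2 - 2 * t3, 0)
}

cif_report <- function(fit, ages) {
  z <- stats::qnorm(1 - (1 - fit$conf_level) / 2)
  st <- fit$steps
  do.call(rbind, lapply(seq_along(fit$causes), function(k) {
    f <- step_at(st$time, fit$Fk[, k], ages, 0)
    v <- vapply(ages, function(t) cif_variance_at(fit, k, t), numeric(1))
    lower <- upper <- rep(NA_real_, length(ages))
    inner <- f > 0 & f < 1
    se_cll <- sqrt(v[inner]) / abs(f[inner] * log(f[inner]))
    lower[inner] <- f[inner]^exp(z * se_cll)
    upper[inner] <- f[inner]^exp(-z * se_cll)
    lower[f == 0] <- 0
    data.frame(cause = fit$causes[k], age = ages, cif = f,
               lower = lower, upper = upper, stringsAsFactors = FALSE)
  }))
}

#' Evaluate a cumulative incidence fit at arbitrary ages
#' @param fit a `cif_fit`.
#' @param ages evaluation ages.
#' @param cause cause label (default first cause).
#' @export
cif_at <- function(fit, ages, cause = fit$causes[1]) {
  k <- match(cause, fit$causes)
  step_at(fit$steps$time, fit$Fk[, k], ages, 0)
}

#' @export
print.cif_fit <- function(x, ...) {
  cat("<cif_fit>", x$n, "subjects, causes:",
      paste(x$causes, collapse = ", "), "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
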