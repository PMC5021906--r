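## Nonparametric toolkit: Kaplan-Meier estimation, plateau-based cure
## fraction, sufficiency-of-follow-up testing, two-sample log-rank.
## Product-limit estimation and the log-rank statistic are delegated to
## the survival package; the thin wrappers fix the return contracts used
## throughout this package.

#' Kaplan-Meier product-limit estimator
#'
#' Computes the right-continuous step estimate
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`.
#' Tied events at one time are grouped; at a time shared by events and
#' censorings, the events are taken to precede the censorings (the
#' censored subjects are still in the risk set at that time).
#'
#' @param time nonnegative follow-up times.
#' @param event 0/1 event indicator.
#' @return An object of class `"step_survival"`: a list with
#'   `jump_times` (distinct event times, increasing), `values` (the
#'   survival level just after each jump), `n_at_risk` and `n_events` per
#'   jump, and `n` subjects.  Query it at arbitrary times with
#'   [step_survival_at()].
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop("empty input")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)),
            all(time >= 0))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.type = "none")
  keep <- sf$n.event > 0
  structure(list(jump_times = sf$time[keep],
                 values = sf$surv[keep],
                 n_at_risk = sf$n.risk[keep],
                 n_events = sf$n.event[keep],
                 n = length(time)),
            class = "step_survival")
}

#' Evaluate a step survival function
#'
#' Right-continuous evaluation: `S(t)` is the level after the last jump at
#' or before `t`, and 1 before the first jump.
#'
#' @param surv a `"step_survival"`.
#' @param t nonnegative time(s).
#' @return Survival probabilities.
#' @export
step_survival_at <- function(surv, t) {
  stopifnot(inherits(surv, "step_survival"), all(t >= 0))
  idx <- findInterval(t, surv$jump_times)
  c(1, surv$values)[idx + 1L]
}

#' @export
print.step_survival <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d event times\n",
              x$n, length(x$jump_times)))
  if (length(x$jump_times))
    cat(sprintf("  plateau S = %.4f at last event time %g\n",
                x$values[length(x$values)],
                x$jump_times[length(x$jump_times)]))
  invisible(x)
}

#' Export a step survival function as a data frame
#'
#' @param x a `"step_survival"`.
#' @param ... unused.
#' @return Data frame with columns `time`, `survival`, `n_at_risk`,
#'   `n_events`, one row per jump.
#' @export
as.data.frame.step_survival <- function(x, ...) {
  data.frame(time = x$jump_times, survival = x$values,
             n_at_risk = x$n_at_risk, n_events = x$n_events)
}

#' Cure-fraction estimate from the Kaplan-Meier plateau
#'
#' With sufficient follow-up, the level at which the Kaplan-Meier curve
#' stabilizes — its value at the largest event time — is a consistent
#' estimator of the nonsusceptible (cured) proportion.
#'
#' @param surv a `"step_survival"` from [kaplan_meier()].
#' @return The plateau survival level, in `[0, 1]`.  If the input has no
#'   events the plateau is trivially 1 and a warning is issued.
#' @export
km_plateau_cure_estimate <- function(surv) {
  stopifnot(inherits(surv, "step_survival"))
  if (!length(surv$jump_times)) {
    warning("no events observed; plateau estimate is trivially 1")
    return(1)
  }
  surv$values[length(surv$values)]
}

#' Test for sufficiency of follow-up
#'
#' Nonparametric check that the follow-up extends long enough past the
#' last event for a Kaplan-Meier plateau to identify a cured fraction.
#' With `t_max` the largest observed time and `t*_max` the largest event
#' time, it counts the `N` events in `[2 t*_max - t_max, t*_max]` and sets
#' `q = N / n`.  When the censoring horizon runs well past the last event
#' the interval is wide and captures many events, so `q` is large and the
#' approximate tail probability `(1 - q)^n` is small: small values are
#' evidence of sufficient follow-up.  When follow-up stops at the last
#' event the interval collapses, `q` is small and the test cannot support
#' sufficiency.
#'
#' @param time,event survival columns (at least one event required).
#' @param alpha significance level for the sufficiency call (default 0.05).
#' @return List with `N_interval`, `q`, `p_value` and logical
#'   `sufficient` (`p_value < alpha`).
#' @export
alpha_test_sufficient_followup <- function(time, event, alpha = 0.05) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  if (!any(event == 1)) stop("no events: follow-up test undefined")
  n <- length(time)
  t_max <- max(time)
  t_star <- max(time[event == 1])
  lo <- 2 * t_star - t_max
  ## closed left endpoint keeps the boundary case t_max == t*_max (the
  ## interval degenerating onto {t*_max}) counting the events there
  N <- sum(event == 1 & time >= lo & time <= t_star)
  q <- N / n
  p <- (1 - q)^n
  list(N_interval = N, q = q, p_value = p, sufficient = p < alpha)
}

#' Two-sample log-rank test
#'
#' Standard 1-df log-rank chi-square comparing two survival curves, with
#' the hypergeometric variance at each distinct event time.
#'
#' @param times_a,events_a survival columns of the first group.
#' @param times_b,events_b survival columns of the second group.
#' @return List with `chi2` and `p_value`.
#' @export
log_rank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be nonempty")
  ev <- c(events_a, events_b)
  if (!any(ev == 1)) stop("no events: log-rank test undefined")
  tm <- c(times_a, times_b)
  g <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  chi2 <- as.numeric(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1,
                                            lower.tail = FALSE))
}
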