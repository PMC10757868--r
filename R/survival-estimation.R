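#' Kaplan-Meier curve of cumulative recurrence incidence
#'
#' Product-limit estimate of recurrence-free survival with Greenwood
#' variance and symmetric normal-approximation 95% confidence bands on the
#' probability scale, truncated to \[0, 1\]. At tied times events precede
#' censorings (standard product-limit convention). The plain (linear)
#' confidence scale is used throughout the package because symmetric bands
#' are what threshold z-tests reconstruct from.
#'
#' @param cohort A cohort tibble.
#' @param conf_level Confidence level for the bands.
#' @return A tibble (class `vpm_survcurve`) with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `std_err` (Greenwood SE of the survival probability), `ci_low`,
#'   `ci_high`.
#' @examples
#' coh <- generate_study_like(seed = 1, n = 200)
#' km <- kaplan_meier(coh)
#' cumulative_incidence_at(km, 12)
#' @export
kaplan_meier <- function(cohort, conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  ev <- event_indicator(cohort)
  if (all(cohort$time_months == 0) && sum(ev) == 0) {
    abort("degenerate cohort: all follow-up times are zero with no events")
  }
  fit <- survival::survfit(survival::Surv(cohort$time_months, ev) ~ 1,
                           conf.type = "none")
  z <- qnorm(1 - (1 - conf_level) / 2)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- cumsum(ifelse(fit$n.risk > fit$n.event,
                      fit$n.event / (fit$n.risk * (fit$n.risk - fit$n.event)),
                      0))
  se <- fit$surv * sqrt(gw)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv,
    std_err = se,
    ci_low = pmax(0, fit$surv - z * se),
    ci_high = pmin(1, fit$surv + z * se)
  )
  class(out) <- c("vpm_survcurve", class(out))
  attr(out, "n") <- nrow(cohort)
  attr(out, "conf_level") <- conf_level
  out
}

# right-continuous lookup of a survcurve column at time t
surv_lookup <- function(curve, col, t, default) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, default, curve[[col]][pmax(idx, 1)])
}

#' Cumulative incidence at a horizon
#'
#' Reads `1 - S(t)` (right-continuous) with its confidence interval off a
#' Kaplan-Meier curve.
#'
#' @param curve A [kaplan_meier()] result.
#' @param t Horizon in months, within the observed follow-up.
#' @return One-row tibble: `time`, `estimate`, `se`, `ci_low`, `ci_high`
#'   on the cumulative-incidence scale.
#' @export
cumulative_incidence_at <- function(curve, t) {
  stopifnot(inherits(curve, "vpm_survcurve"))
  assert_scalar_number(t, "t", lower = 0)
  if (t > max(curve$time) + 1e-9) {
    abort(sprintf("t = %g months is beyond the last observed time (%g)",
                  t, max(curve$time)))
  }
  tibble::tibble(
    time = t,
    estimate = 1 - surv_lookup(curve, "survival", t, 1),
    se = surv_lookup(curve, "std_err", t, 0),
    ci_low = 1 - surv_lookup(curve, "ci_high", t, 1),
    ci_high = 1 - surv_lookup(curve, "ci_low", t, 1)
  )
}

#' Plot a Kaplan-Meier cumulative incidence curve
#'
#' @param object A [kaplan_meier()] result.
#' @param ... Unused.
#' @return A ggplot of cumulative incidence with dashed confidence bands.
#' @export
autoplot.vpm_survcurve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1, ci_low = 1, ci_high = 1),
    object
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_step(ggplot2::aes(y = 1 - .data$survival)) +
    ggplot2::geom_step(ggplot2::aes(y = 1 - .data$ci_low), linetype = "dashed") +
    ggplot2::geom_step(ggplot2::aes(y = 1 - .data$ci_high), linetype = "dashed") +
    ggplot2::labs(x = "Months since anticoagulation discontinuation",
                  y = "Cumulative recurrence incidence") +
    ggplot2::theme_minimal()
}

#' Actuarial (life-table) interval recurrence rate
#'
#' Conditional probability of recurrence within `[t0, t1)` for patients at
#' risk at `t0`, treating within-interval censorings as half-exposed:
#' `d / (n - c/2)` with `d` events and `c` censorings in the interval.
#'
#' @param cohort A cohort tibble.
#' @param t0,t1 Interval bounds in months, `t0 < t1`.
#' @return One-row tibble: `t0`, `t1`, `n_at_risk`, `events`, `censored`,
#'   `rate`.
#' @export
actuarial_interval_rate <- function(cohort, t0, t1) {
  cohort <- validate_cohort(cohort)
  assert_scalar_number(t0, "t0", lower = 0)
  assert_scalar_number(t1, "t1")
  if (t1 <= t0) abort("need t0 < t1")
  ev <- event_indicator(cohort)
  at_risk <- cohort$time_months >= t0
  n <- sum(at_risk)
  if (n == 0) abort(sprintf("no patients at risk at t0 = %g months", t0))
  in_int <- at_risk & cohort$time_months < t1
  d <- sum(in_int & ev == 1)
  cns <- sum(in_int & ev == 0)
  tibble::tibble(t0 = t0, t1 = t1, n_at_risk = n, events = d, censored = cns,
                 rate = d / (n - cns / 2))
}

#' Person-time incidence rate with exact Poisson confidence interval
#'
#' Events and person-time accrued within `[t0, t1)`; the rate is reported
#' per 100 person-years (1 year = 12 months) with the exact Poisson CI by
#' chi-square inversion.
#'
#' @param cohort A cohort tibble.
#' @param t0,t1 Interval bounds in months.
#' @param conf_level Confidence level.
#' @return One-row tibble: `events`, `person_years`, `rate_per_100py`,
#'   `ci_low`, `ci_high`.
#' @export
person_time_rate <- function(cohort, t0 = 0, t1 = 24, conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  if (t1 <= t0) abort("need t0 < t1")
  ev <- event_indicator(cohort)
  exposure <- pmax(0, pmin(cohort$time_months, t1) - t0)
  py <- sum(exposure) / 12
  if (py <= 0) abort("zero person-time in the interval")
  d <- sum(ev == 1 & cohort$time_months >= t0 & cohort$time_months < t1)
  a <- (1 - conf_level) / 2
  lo <- if (d == 0) 0 else qchisq(a, 2 * d) / 2
  hi <- qchisq(1 - a, 2 * (d + 1)) / 2
  tibble::tibble(events = d, person_years = py,
                 rate_per_100py = 100 * d / py,
                 ci_low = 100 * lo / py, ci_high = 100 * hi / py)
}

#' One-sample threshold z-test
#'
#' Tests the null hypothesis that a cumulative risk is at or above
#' `null_value` against the one-sided alternative that it is below, using
#' a normal approximation: `z = (estimate - null_value)/se`, lower-tail p.
#' The natural `se` is the Greenwood standard error of the Kaplan-Meier
#' estimate at the horizon; an `se` reconstructed from a printed symmetric
#' confidence interval, `(ci_high - ci_low)/(2 * 1.96)`, is equivalent.
#'
#' @param estimate Estimated cumulative risk (probability).
#' @param se Standard error of the estimate, `> 0`.
#' @param null_value Threshold risk under the null.
#' @return One-row tibble: `estimate`, `se`, `null_value`, `z`,
#'   `p_one_sided`.
#' @examples
#' # from a printed 5.2% (95% CI 3.2-7.2) vs an 8% threshold:
#' threshold_z_test(0.052, (0.072 - 0.032) / (2 * qnorm(0.975)), 0.08)
#' @export
threshold_z_test <- function(estimate, se, null_value) {
  assert_scalar_number(estimate, "estimate", 0, 1)
  assert_scalar_number(null_value, "null_value", 0, 1)
  if (!is_scalar_number(se) || se <= 0) abort("`se` must be a positive number")
  z <- (estimate - null_value) / se
  tibble::tibble(estimate = estimate, se = se, null_value = null_value,
                 z = z, p_one_sided = pnorm(z))
}
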