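#' Calibration slope of an external risk model
#'
#' Cox regression of the validation cohort on the model's linear predictor
#' as a single covariate. A slope of 1 means the model's predictor weights
#' are correctly scaled for the new cohort; below 1 they are too extreme,
#' above 1 too shrunken.
#'
#' @param cohort A cohort tibble.
#' @param lp Per-subject linear predictors of the model under validation.
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble: `slope`, `std_error`, `ci_low`, `ci_high`,
#'   `n`, `n_events`.
#' @export
calibration_slope <- function(cohort, lp, conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  lp <- as.numeric(lp)
  if (length(lp) != nrow(cohort)) abort("`lp` must have one value per patient")
  if (var(lp) == 0) abort("linear predictor has zero variance")
  if (sum(event_indicator(cohort)) < 2) abort("need at least 2 events")
  fit <- fit_cox(dplyr::mutate(cohort, .lp = lp), covariates = ".lp")
  td <- tidy(fit, conf_level = conf_level)
  tibble::tibble(slope = td$estimate, std_error = td$std_error,
                 ci_low = td$conf_low, ci_high = td$conf_high,
                 n = fit$n, n_events = fit$n_events)
}

# expected event count under a model: cumulative-hazard scale,
# E = sum_i H0(min(t_i, horizon)) * exp(lp_i). Each subject contributes
# expected events only over their own follow-up, so censoring does not
# inflate E, and Breslow recalibration makes O/E exactly 1.
expected_events <- function(cohort, model, horizon) {
  lp <- vpm_linear_predictor(cohort, model)
  tt <- pmin(cohort$time_months, horizon)
  sum(baseline_cumhaz(model$baseline, tt) * exp(lp))
}

#' Observed/expected event ratio
#'
#' Ratio of observed recurrences within the horizon to the number of
#' events the model expects over the cohort's actual follow-up,
#' `E = sum_i H0(min(t_i, horizon)) exp(lp_i)` on the cumulative-hazard
#' scale. O/E above 1 means the model underestimates risk. The confidence
#' interval (when `n_boot > 0`) is a percentile bootstrap over patients.
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @param horizon Months (\eqn{\le} baseline domain).
#' @param n_boot Bootstrap resamples for the CI; 0 skips the CI.
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return One-row tibble: `observed`, `expected`, `oe`, `ci_low`,
#'   `ci_high` (the CI columns are `NA` when `n_boot = 0`).
#' @export
oe_ratio <- function(cohort, model, horizon = 24, n_boot = 0, seed = NULL,
                     conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(model, "vpm_definition"))
  if (horizon > model$baseline$domain) abort("horizon beyond baseline domain")
  ev <- event_indicator(cohort)
  observed <- sum(ev == 1 & cohort$time_months <= horizon)
  expected <- expected_events(cohort, model, horizon)
  if (expected <= 0) {
    if (observed == 0) {
      return(tibble::tibble(observed = 0, expected = 0, oe = 0,
                            ci_low = NA_real_, ci_high = NA_real_))
    }
    abort("model expects zero events but events were observed")
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    lp <- vpm_linear_predictor(cohort, model)
    contrib <- baseline_cumhaz(model$baseline,
                               pmin(cohort$time_months, horizon)) * exp(lp)
    obs_i <- as.numeric(ev == 1 & cohort$time_months <= horizon)
    n <- nrow(cohort)
    reps <- with_local_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      e_b <- sum(contrib[idx])
      if (e_b <= 0) return(NA_real_)
      sum(obs_i[idx]) / e_b
    }, numeric(1)))
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(reps, c(a, 1 - a), na.rm = TRUE, type = 7))
  }
  tibble::tibble(observed = observed, expected = expected,
                 oe = observed / expected, ci_low = ci[1], ci_high = ci[2])
}

# Kaplan-Meier of the censoring distribution (censorings as events), as a
# right-continuous step function; tie rule mirrors the event-side
# convention: censorings precede events at tied times
censoring_km <- function(time, ev) {
  fit <- survival::survfit(survival::Surv(time, 1 - ev) ~ 1, conf.type = "none")
  if (length(fit$time) == 0) return(function(t) rep(1, length(t)))
  stepfun(fit$time, c(1, fit$surv), right = FALSE)
}

#' Uno's IPCW concordance index
#'
#' Censoring-robust c-statistic up to a truncation time `tau`: over pairs
#' `(i, j)` with `t_i < t_j`, `t_i < tau`, subject `i` an event, each pair
#' is weighted by `1 / G(t_i)^2` where `G` is the Kaplan-Meier estimate of
#' the censoring distribution; a pair is concordant when `lp_i > lp_j`,
#' ties in `lp` count one half. Without censoring this reduces to
#' Harrell's concordance.
#'
#' @param cohort A cohort tibble.
#' @param lp Per-subject linear predictors (higher = riskier).
#' @param tau Truncation time, months.
#' @return Scalar concordance in `[0, 1]`.
#' @export
uno_c <- function(cohort, lp, tau = 24) {
  cohort <- validate_cohort(cohort)
  lp <- as.numeric(lp)
  if (length(lp) != nrow(cohort)) abort("`lp` must have one value per patient")
  time <- cohort$time_months
  ev <- event_indicator(cohort)
  if (!any(ev == 1 & time < tau)) abort("no events before tau")
  G <- censoring_km(time, ev)
  num <- 0
  den <- 0
  ii <- which(ev == 1 & time < tau)
  g <- G(time[ii])
  if (any(g <= 0)) {
    abort("censoring survival G(t) is 0 at an event time; lower `tau`")
  }
  for (k in seq_along(ii)) {
    i <- ii[k]
    w <- 1 / g[k]^2
    later <- time > time[i]
    if (!any(later)) next
    conc <- sum(lp[i] > lp[later]) + 0.5 * sum(lp[i] == lp[later])
    num <- num + w * conc
    den <- den + w * sum(later)
  }
  if (den == 0) abort("no comparable pairs before tau")
  num / den
}

#' Grouped calibration table
#'
#' Groups patients by quantiles of predicted risk at the horizon and
#' compares, per group, the mean predicted cumulative incidence with the
#' observed Kaplan-Meier cumulative incidence and its confidence interval.
#' A group whose risk set is exhausted before the horizon is flagged (the
#' last available Kaplan-Meier value is reported), not dropped.
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @param horizon Months.
#' @param n_groups Number of quantile groups (default quintiles).
#' @return A tibble (class `vpm_calibration`): `group`, `n`, `n_events`,
#'   `mean_predicted`, `observed`, `ci_low`, `ci_high`, `flagged`.
#' @export
calibration_table <- function(cohort, model, horizon = 24, n_groups = 5) {
  cohort <- validate_cohort(cohort)
  if (n_groups < 1) abort("`n_groups` must be >= 1")
  lp <- vpm_linear_predictor(cohort, model)
  pred <- predicted_risk(model, lp, horizon)
  grp <- if (n_groups == 1) rep(1L, nrow(cohort)) else
    dplyr::ntile(pred, n_groups)
  rows <- purrr::map(seq_len(n_groups), function(g) {
    sel <- grp == g
    sub <- cohort[sel, , drop = FALSE]
    km <- kaplan_meier(sub)
    flagged <- max(km$time) < horizon
    at <- cumulative_incidence_at(km, min(horizon, max(km$time)))
    tibble::tibble(group = g, n = nrow(sub),
                   n_events = sum(event_indicator(sub)),
                   mean_predicted = mean(pred[sel]),
                   observed = at$estimate, ci_low = at$ci_low,
                   ci_high = at$ci_high, flagged = flagged)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("vpm_calibration", class(out))
  attr(out, "horizon") <- horizon
  out
}

#' Plot a grouped calibration table
#'
#' @param object A [calibration_table()] result.
#' @param ... Unused.
#' @return A ggplot of observed vs mean predicted risk per group with the
#'   identity line.
#' @export
autoplot.vpm_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "Mean predicted cumulative incidence",
                  y = "Observed cumulative incidence (KM)") +
    ggplot2::theme_minimal()
}

#' Full external-validation report
#'
#' Calibration slope, observed/expected ratio (with bootstrap CI), Uno's
#' concordance and a grouped calibration table for one model on one
#' cohort.
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @param horizon Calibration horizon, months.
#' @param tau Truncation time for Uno's c, months.
#' @param n_groups Calibration groups.
#' @param n_boot Bootstrap resamples for the O/E CI.
#' @param seed RNG seed for the bootstrap.
#' @return A `vpm_validation` object; see [tidy.vpm_validation()] and
#'   [glance.vpm_validation()].
#' @examples
#' coh <- generate_study_like(seed = 7, n = 400)
#' validate_model(coh, vpm_definition(), n_boot = 50, seed = 1)
#' @export
validate_model <- function(cohort, model, horizon = 24, tau = 24,
                           n_groups = 5, n_boot = 1000, seed = NULL) {
  cohort <- validate_cohort(cohort)
  lp <- vpm_linear_predictor(cohort, model)
  structure(list(
    slope = calibration_slope(cohort, lp),
    oe = oe_ratio(cohort, model, horizon = horizon, n_boot = n_boot,
                  seed = seed),
    uno_c = uno_c(cohort, lp, tau = tau),
    calibration = calibration_table(cohort, model, horizon = horizon,
                                    n_groups = n_groups),
    horizon = horizon, tau = tau,
    n = nrow(cohort), n_events = sum(event_indicator(cohort)),
    n_boot = n_boot, seed = seed
  ), class = "vpm_validation")
}

#' @export
print.vpm_validation <- function(x, ...) {
  cat(sprintf("<vpm_validation> n = %d, events = %d, horizon = %g months\n",
              x$n, x$n_events, x$horizon))
  cat(sprintf("  calibration slope: %.2f (95%% CI %.2f-%.2f)\n",
              x$slope$slope, x$slope$ci_low, x$slope$ci_high))
  cat(sprintf("  O/E: %d / %.1f = %.2f", x$oe$observed, x$oe$expected, x$oe$oe))
  if (!is.na(x$oe$ci_low)) {
    cat(sprintf(" (95%% CI %.2f-%.2f)", x$oe$ci_low, x$oe$ci_high))
  }
  cat(sprintf("\n  Uno's c (tau = %g): %.3f\n", x$tau, x$uno_c))
  invisible(x)
}

#' Tidy / glance a validation report
#'
#' @param x A `vpm_validation` from [validate_model()].
#' @param ... Unused.
#' @return `tidy()`: the grouped calibration table; `glance()`: one row
#'   with the headline metrics.
#' @export
tidy.vpm_validation <- function(x, ...) {
  tibble::as_tibble(x$calibration)
}

#' @rdname tidy.vpm_validation
#' @export
glance.vpm_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, horizon = x$horizon,
    calibration_slope = x$slope$slope,
    slope_ci_low = x$slope$ci_low, slope_ci_high = x$slope$ci_high,
    observed = x$oe$observed, expected = x$oe$expected, oe = x$oe$oe,
    oe_ci_low = x$oe$ci_low, oe_ci_high = x$oe$ci_high,
    uno_c = x$uno_c
  )
}
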