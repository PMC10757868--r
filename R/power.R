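# Kaplan-Meier cumulative incidence and Greenwood SE at a single horizon,
# minimal and fast for resampled trials. Returns NA estimate when the risk
# set is exhausted before the horizon.
km_at_horizon <- function(time, ev, horizon) {
  keep <- ev == 1 & time <= horizon
  if (!any(keep)) {
    if (max(time) < horizon && sum(time >= horizon) == 0) {
      # all follow-up ended before the horizon without events: undefined
      return(c(estimate = NA_real_, se = NA_real_))
    }
    return(c(estimate = 0, se = 0))
  }
  ord <- order(time)
  time_s <- time[ord]
  ev_s <- ev[ord]
  n <- length(time_s)
  ev_times <- unique(time_s[ev_s == 1 & time_s <= horizon])
  n_risk <- n - findInterval(ev_times, time_s, left.open = TRUE)
  d <- vapply(ev_times, function(t) sum(ev_s == 1 & time_s == t), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  gw <- cumsum(d / (n_risk * (n_risk - d)))
  s <- surv[length(surv)]
  c(estimate = 1 - s, se = s * sqrt(gw[length(gw)]))
}

#' Simulation-based power of a one-sided threshold design
#'
#' Estimates, by trial simulation, the power of a single-arm cohort study
#' to show that the cumulative recurrence risk at a horizon is below a
#' threshold. Each simulated trial draws `n_per_trial` patients with
#' replacement from a reference cohort, computes the Kaplan-Meier
#' cumulative incidence and its Greenwood standard error at the horizon,
#' and rejects the null (`risk >= null_value`) when the one-sided
#' [threshold_z_test()] p-value is below `alpha`. Power is the rejection
#' fraction; its simulation standard error is
#' `sqrt(power (1 - power) / n_trials)`. A trial whose Kaplan-Meier
#' estimate is undefined at the horizon (risk set exhausted earlier)
#' counts conservatively as a non-rejection; a trial with zero events and
#' follow-up past the horizon rejects (estimate 0 below any positive
#' threshold).
#'
#' @param reference Reference cohort to resample from (e.g.
#'   [generate_historical()]).
#' @param n_per_trial Patients per simulated trial.
#' @param n_trials Number of simulated trials (>= 100).
#' @param horizon Months.
#' @param null_value Threshold cumulative risk under the null.
#' @param alpha One-sided significance level.
#' @param seed RNG seed (required).
#' @return A one-row tibble (class `vpm_power`): `power`, `sim_se`,
#'   `n_trials`, `n_per_trial`, `horizon`, `null_value`,
#'   `alpha_one_sided`, `n_undefined`, `seed`.
#' @examples
#' ref <- generate_historical(seed = 3, n = 2000)
#' simulate_power(ref, n_per_trial = 500, n_trials = 200, seed = 11)
#' @export
simulate_power <- function(reference, n_per_trial = 500, n_trials = 1000,
                           horizon = 12, null_value = 0.08, alpha = 0.025,
                           seed) {
  reference <- validate_cohort(reference)
  if (n_trials < 100) abort("`n_trials` must be >= 100")
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(null_value, "null_value", 0, 1)
  ev <- event_indicator(reference)
  if (!any(ev == 1 & reference$time_months <= horizon)) {
    abort("reference cohort has no events before the horizon")
  }
  time <- reference$time_months
  n_ref <- nrow(reference)
  z_alpha <- qnorm(alpha)
  res <- with_local_seed(seed, vapply(seq_len(n_trials), function(b) {
    idx <- sample.int(n_ref, n_per_trial, replace = TRUE)
    km <- km_at_horizon(time[idx], ev[idx], horizon)
    if (is.na(km["estimate"])) return(c(reject = 0, undef = 1))
    if (km["se"] == 0) {
      return(c(reject = as.numeric(km["estimate"] < null_value), undef = 0))
    }
    z <- (km["estimate"] - null_value) / km["se"]
    c(reject = as.numeric(z < z_alpha), undef = 0)
  }, numeric(2)))
  power <- mean(res["reject", ])
  out <- tibble::tibble(
    power = power,
    sim_se = sqrt(power * (1 - power) / n_trials),
    n_trials = n_trials, n_per_trial = n_per_trial, horizon = horizon,
    null_value = null_value, alpha_one_sided = alpha,
    n_undefined = sum(res["undef", ]), seed = as.integer(seed)
  )
  class(out) <- c("vpm_power", class(out))
  out
}

#' Power curve over a grid of trial sizes
#'
#' Runs [simulate_power()] for each trial size; sub-seeds `seed + i` keep
#' the grid reproducible while varying across sizes.
#'
#' @param reference Reference cohort.
#' @param n_grid Trial sizes.
#' @param ... Passed to [simulate_power()].
#' @param seed RNG seed.
#' @return A `vpm_power` tibble with one row per trial size.
#' @export
power_curve <- function(reference, n_grid, ..., seed) {
  out <- purrr::list_rbind(purrr::imap(as.integer(n_grid), function(n, i) {
    simulate_power(reference, n_per_trial = n, ...,
                   seed = as.integer(seed) + i)
  }))
  class(out) <- c("vpm_power", class(out))
  out
}

#' Plot a power curve
#'
#' @param object A [power_curve()] result.
#' @param ... Unused.
#' @return A ggplot of power (with +/- 1 simulation SE) vs trial size.
#' @export
autoplot.vpm_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_per_trial, y = .data$power)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$power - .data$sim_se,
                                          ymax = .data$power + .data$sim_se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Patients per trial", y = "Simulated power") +
    ggplot2::theme_minimal()
}
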