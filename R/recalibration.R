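#' Lack-of-fit test for fixed predictor weights
#'
#' Fits a Cox model with the model's own covariates (male sex, proximal
#' DVT, pulmonary embolism, log2 D-dimer) while the model's linear
#' predictor enters as an offset with weight fixed at 1. The fitted
#' coefficients are then the *modifications* the cohort suggests to the
#' existing predictor weights (all zero for an ideal fit), and a
#' likelihood-ratio test against the offset-only model (df = 4) tests
#' whether any modification is needed.
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @return A `vpm_lack_of_fit` object: `deltas` (tibble of suggested
#'   weight changes with SEs and Wald CIs), `statistic`, `df`, `p_value`.
#' @export
lack_of_fit_test <- function(cohort, model) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(model, "vpm_definition"))
  lp <- vpm_linear_predictor(cohort, model)
  dat <- dplyr::mutate(
    cohort,
    male = as.numeric(.data$sex == "male"),
    proximal = as.numeric(.data$site == "proximal_dvt"),
    pe = as.numeric(.data$site == "pulmonary_embolism"),
    log2_ddimer = log2(.data$ddimer_ng_ml)
  )
  n_events <- sum(event_indicator(cohort))
  if (n_events < 20) {
    warn(sprintf(
      "only %d events for 4 free parameters (< 5 per parameter); estimates may be unstable",
      n_events))
  }
  full <- fit_cox(dat, covariates = c("male", "proximal", "pe", "log2_ddimer"),
                  offset = lp)
  reduced <- fit_cox(dat, covariates = character(), offset = lp)
  lrt <- likelihood_ratio_test(full, reduced, df = 4)
  structure(list(deltas = tidy(full), statistic = lrt$statistic,
                 df = lrt$df, p_value = lrt$p_value,
                 n = nrow(cohort), n_events = n_events),
            class = "vpm_lack_of_fit")
}

#' @export
print.vpm_lack_of_fit <- function(x, ...) {
  cat(sprintf(
    "<vpm_lack_of_fit> LRT chi-square = %.3f, df = %d, p = %.3g (n = %d, events = %d)\n",
    x$statistic, x$df, x$p_value, x$n, x$n_events))
  print(x$deltas)
  invisible(x)
}

#' @export
tidy.vpm_lack_of_fit <- function(x, ...) x$deltas

#' @export
glance.vpm_lack_of_fit <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = x$n, n_events = x$n_events)
}

#' Recalibrate a model's baseline hazard on a cohort
#'
#' Leaves the predictor weights untouched and replaces the baseline
#' survival by the Breslow estimate computed from the cohort with the
#' model's linear predictors held fixed. After recalibration the
#' observed/expected ratio on the same cohort is exactly 1. The 1-year
#' risk threshold is re-derived from the (unchanged) points threshold
#' under the new baseline, keeping the two gates equivalent.
#'
#' @param cohort A cohort tibble with at least one event.
#' @param model A [vpm_definition()].
#' @param domain Domain of the recalibrated baseline, months.
#' @return A new `vpm_definition` with the recalibrated baseline.
#' @export
recalibrate_baseline <- function(cohort, model, domain = 24) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(model, "vpm_definition"))
  lp <- vpm_linear_predictor(cohort, model)
  bh <- breslow_baseline(cohort, lp)
  out <- model
  out$baseline <- baseline_to_survival(bh, domain = domain)
  out$label <- paste0(model$label, "+recalibrated")
  # keep the points gate primary; re-derive the equivalent 1-year risk gate
  lp_star <- (out$points_threshold - out$points_intercept) / out$points_slope
  out$risk_threshold_1y <- predicted_risk(out, lp_star, min(12, domain))
  out
}

# resample rows with replacement (fresh patient ids), redrawing until the
# resample has >= 1 event
resample_with_events <- function(cohort, n_redrawn_env = NULL) {
  n <- nrow(cohort)
  ev <- event_indicator(cohort)
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(ev[idx]) > 0) break
    if (!is.null(n_redrawn_env)) {
      n_redrawn_env$count <- n_redrawn_env$count + 1L
    }
  }
  boot <- cohort[idx, , drop = FALSE]
  boot$patient_id <- sprintf("b%06d", seq_len(n))
  boot
}

#' Bootstrap confidence bands for a recalibrated baseline
#'
#' Resamples patients with replacement, recalibrates the baseline on each
#' resample, and takes pointwise percentile bands of the cumulative
#' baseline risk `1 - S0(t)` on a fixed monthly grid. Resamples with zero
#' events are redrawn (the count is recorded in the `n_redrawn`
#' attribute).
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @param n_boot Number of resamples (>= 100 recommended; default 1000).
#' @param seed RNG seed (required: bands must be reproducible).
#' @param grid Evaluation grid in months.
#' @param conf_level Confidence level of the pointwise bands.
#' @return A tibble (class `vpm_baseline_ci`): `time`, `estimate`,
#'   `ci_low`, `ci_high` of the cumulative baseline risk.
#' @export
bootstrap_baseline_ci <- function(cohort, model, n_boot = 1000, seed,
                                  grid = 0:24, conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  if (n_boot < 2) abort("`n_boot` must be at least 2")
  point <- recalibrate_baseline(cohort, model, domain = max(grid))
  est <- 1 - baseline_survival(point$baseline, grid)
  redrawn <- new.env()
  redrawn$count <- 0L
  reps <- with_local_seed(seed, vapply(seq_len(n_boot), function(b) {
    boot <- resample_with_events(cohort, redrawn)
    m_b <- recalibrate_baseline(boot, model, domain = max(grid))
    1 - baseline_survival(m_b$baseline, grid)
  }, numeric(length(grid))))
  a <- (1 - conf_level) / 2
  out <- tibble::tibble(
    time = grid, estimate = est,
    ci_low = apply(reps, 1, quantile, probs = a, type = 7),
    ci_high = apply(reps, 1, quantile, probs = 1 - a, type = 7)
  )
  class(out) <- c("vpm_baseline_ci", class(out))
  attr(out, "n_redrawn") <- redrawn$count
  attr(out, "n_boot") <- n_boot
  out
}

#' Plot bootstrap baseline bands
#'
#' @param object A [bootstrap_baseline_ci()] result.
#' @param ... Unused.
#' @return A ggplot of cumulative baseline risk with percentile bands.
#' @export
autoplot.vpm_baseline_ci <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_step(ggplot2::aes(y = .data$estimate)) +
    ggplot2::labs(x = "Months", y = "Cumulative baseline risk 1 - S0(t)") +
    ggplot2::theme_minimal()
}

#' Optimism-corrected O/E ratio of the recalibrated model
#'
#' Harrell's optimism-correcting bootstrap for the observed/expected ratio
#' after baseline recalibration. The apparent O/E of a model recalibrated
#' on the full cohort is exactly 1; each bootstrap resample recalibrates
#' on the resample, evaluates O/E on the resample (apparent) and on the
#' original cohort (test), and the mean apparent-minus-test gap is the
#' optimism subtracted from the apparent value. The CI is the percentile
#' interval of the corrected replicates.
#'
#' @param cohort A cohort tibble with at least one event.
#' @param model A [vpm_definition()].
#' @param horizon Months.
#' @param n_boot Number of resamples.
#' @param seed RNG seed (required).
#' @param conf_level Confidence level.
#' @return One-row tibble: `oe_apparent`, `optimism`, `oe_corrected`,
#'   `ci_low`, `ci_high`, `n_boot`.
#' @export
optimism_corrected_oe <- function(cohort, model, horizon = 24, n_boot = 1000,
                                  seed, conf_level = 0.95) {
  cohort <- validate_cohort(cohort)
  if (sum(event_indicator(cohort)) == 0) {
    abort("cohort has zero events; O/E undefined")
  }
  recal <- recalibrate_baseline(cohort, model, domain = max(24, horizon))
  apparent <- oe_ratio(cohort, recal, horizon = horizon)$oe
  reps <- with_local_seed(seed, vapply(seq_len(n_boot), function(b) {
    boot <- resample_with_events(cohort)
    m_b <- recalibrate_baseline(boot, model, domain = max(24, horizon))
    apparent_b <- oe_ratio(boot, m_b, horizon = horizon)$oe
    test_b <- oe_ratio(cohort, m_b, horizon = horizon)$oe
    c(apparent_b = apparent_b, test_b = test_b)
  }, numeric(2)))
  optimism <- mean(reps["apparent_b", ] - reps["test_b", ])
  corrected_reps <- apparent - (reps["apparent_b", ] - reps["test_b", ])
  a <- (1 - conf_level) / 2
  ci <- unname(quantile(corrected_reps, c(a, 1 - a), type = 7))
  tibble::tibble(oe_apparent = apparent, optimism = optimism,
                 oe_corrected = apparent - optimism,
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot)
}

#' Full recalibration report
#'
#' Runs the model-updating sequence on a cohort: lack-of-fit test of the
#' predictor weights, Breslow baseline recalibration, bootstrap percentile
#' bands for the recalibrated baseline, and the optimism-corrected O/E
#' ratio.
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @param horizon Months.
#' @param n_boot Bootstrap resamples (both bootstraps).
#' @param seed RNG seed (required).
#' @return A `vpm_recalibration` object with elements `lack_of_fit`,
#'   `model` (the recalibrated definition), `baseline_ci`, `oe_corrected`,
#'   `n_boot`, `seed`.
#' @export
recalibrate <- function(cohort, model, horizon = 24, n_boot = 1000, seed) {
  cohort <- validate_cohort(cohort)
  structure(list(
    lack_of_fit = lack_of_fit_test(cohort, model),
    model = recalibrate_baseline(cohort, model, domain = max(24, horizon)),
    baseline_ci = bootstrap_baseline_ci(cohort, model, n_boot = n_boot,
                                        seed = seed),
    oe_corrected = optimism_corrected_oe(cohort, model, horizon = horizon,
                                         n_boot = n_boot, seed = seed + 1L),
    horizon = horizon, n_boot = n_boot, seed = seed
  ), class = "vpm_recalibration")
}

#' @export
print.vpm_recalibration <- function(x, ...) {
  cat("<vpm_recalibration>\n")
  cat(sprintf("  lack of fit: chi-square = %.2f (df %d), p = %.3g\n",
              x$lack_of_fit$statistic, x$lack_of_fit$df, x$lack_of_fit$p_value))
  cat(sprintf("  recalibrated baseline: S0(%g) = %.4f\n", x$model$baseline$domain,
              baseline_survival(x$model$baseline, x$model$baseline$domain)))
  cat(sprintf("  optimism-corrected O/E: %.2f (95%% CI %.2f-%.2f), %d resamples\n",
              x$oe_corrected$oe_corrected, x$oe_corrected$ci_low,
              x$oe_corrected$ci_high, x$n_boot))
  invisible(x)
}

#' @export
glance.vpm_recalibration <- function(x, ...) {
  tibble::tibble(
    lack_of_fit_statistic = x$lack_of_fit$statistic,
    lack_of_fit_p = x$lack_of_fit$p_value,
    oe_corrected = x$oe_corrected$oe_corrected,
    oe_ci_low = x$oe_corrected$ci_low,
    oe_ci_high = x$oe_corrected$ci_high,
    n_boot = x$n_boot, seed = x$seed
  )
}
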