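#' Fit a Cox proportional-hazards model on a cohort
#'
#' Partial-likelihood fit (Efron tie correction) of recurrence hazard on
#' arbitrary numeric covariate columns, with an optional per-subject
#' offset entering the linear predictor with coefficient fixed at 1 — the
#' construction used by calibration-slope and lack-of-fit analyses, where
#' the offset is the linear predictor of an existing model. Fitting goes
#' through [survival::coxph()]; this wrapper standardises the inputs,
#' surfaces non-convergence and collinearity instead of returning them
#' silently, and exposes the pieces downstream analyses need.
#'
#' @param cohort A cohort tibble, possibly with extra numeric covariate
#'   columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty for an offset-only model).
#' @param offset Optional per-subject offset: a numeric vector of length
#'   `nrow(cohort)` or the name of a column.
#' @return A `vpm_coxfit` object with elements `coefficients`,
#'   `covariance`, `log_partial_likelihood`, `null_log_partial_likelihood`,
#'   `n`, `n_events`, `converged`; see [tidy.vpm_coxfit()].
#' @export
fit_cox <- function(cohort, covariates = character(), offset = NULL) {
  cohort <- validate_cohort(cohort)
  ev <- event_indicator(cohort)
  if (sum(ev) == 0) abort("cannot fit a Cox model with zero events")
  if (is.character(offset) && length(offset) == 1) {
    if (!offset %in% names(cohort)) abort(sprintf("offset column '%s' not found", offset))
    offset <- cohort[[offset]]
  }
  if (!is.null(offset)) {
    offset <- as.numeric(offset)
    if (length(offset) != nrow(cohort) || any(!is.finite(offset))) {
      abort("`offset` must be a finite numeric vector with one value per patient")
    }
  }
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov) > 0) {
    abort(sprintf("covariate column(s) not found: %s",
                  paste(missing_cov, collapse = ", ")))
  }
  if (length(covariates) > 0) {
    X <- as.matrix(dplyr::select(cohort, dplyr::all_of(covariates)))
    storage.mode(X) <- "double"
    if (any(apply(X, 2, function(col) var(col) == 0))) {
      abort("constant covariate column: no information to estimate its weight")
    }
    if (qr(scale(X, scale = FALSE))$rank < ncol(X)) {
      abort("collinear covariates: design matrix is rank deficient")
    }
  }
  if (length(covariates) == 0 && is.null(offset)) {
    abort("need covariates and/or an offset")
  }
  dat <- if (length(covariates) > 0) as.data.frame(X) else
    data.frame(row.names = seq_len(nrow(cohort)))
  dat$.time <- cohort$time_months
  dat$.ev <- ev
  if (!is.null(offset)) dat$.off <- offset
  rhs <- c(covariates, if (!is.null(offset)) "offset(.off)")
  form <- stats::as.formula(
    paste("survival::Surv(.time, .ev) ~", paste(rhs, collapse = " + ")),
    env = environment())
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinit|beta may be infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- stats::coef(fit)
  if (length(coefs) > 0 && any(is.na(coefs))) {
    abort("Cox fit dropped a covariate (collinearity); refit without it")
  }
  ll <- fit$loglik
  structure(list(
    coefficients = coefs,
    covariance = if (length(coefs) > 0) stats::vcov(fit) else
      matrix(0, 0, 0),
    log_partial_likelihood = ll[length(ll)],
    null_log_partial_likelihood = ll[1],
    n = nrow(cohort), n_events = sum(ev),
    converged = converged,
    covariates = covariates, has_offset = !is.null(offset)
  ), class = "vpm_coxfit")
}

#' @export
print.vpm_coxfit <- function(x, ...) {
  cat(sprintf("<vpm_coxfit> n = %d, events = %d, log PL = %.4f%s\n",
              x$n, x$n_events, x$log_partial_likelihood,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$coefficients) > 0) print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `vpm_coxfit`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`.
#' @export
tidy.vpm_coxfit <- function(x, conf_level = 0.95, ...) {
  if (length(x$coefficients) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric(), conf_low = numeric(),
                          conf_high = numeric()))
  }
  se <- sqrt(diag(x$covariance))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std_error = unname(se),
                 conf_low = unname(x$coefficients - z * se),
                 conf_high = unname(x$coefficients + z * se))
}

#' @rdname tidy.vpm_coxfit
#' @export
glance.vpm_coxfit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 log_partial_likelihood = x$log_partial_likelihood,
                 converged = x$converged)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param full,reduced `vpm_coxfit` objects, `reduced` nested in `full`.
#' @param df Difference in free parameters.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced, df) {
  stopifnot(inherits(full, "vpm_coxfit"), inherits(reduced, "vpm_coxfit"))
  stat <- 2 * (full$log_partial_likelihood - reduced$log_partial_likelihood)
  if (stat < -1e-6) {
    abort("full model has lower partial likelihood than reduced: models are not nested")
  }
  stat <- max(stat, 0)
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Breslow cumulative baseline-hazard estimator
#'
#' With predictor weights held fixed (linear predictors supplied, not
#' estimated), the baseline hazard increment at each distinct event time
#' `t` with `d` events is `d / sum(exp(lp_j))` over the risk set at `t`.
#' Satisfies the martingale identity
#' `sum_i H0(t_i) exp(lp_i) = total events` exactly, which is what makes
#' the observed/expected ratio of a recalibrated model exactly 1.
#'
#' @param cohort A cohort tibble with at least one event.
#' @param lp Per-subject linear predictors (finite numeric, one per row).
#' @return A tibble (class `vpm_baseline_hazard`): `time`, `n_event`,
#'   `increment`, `cumhaz` at each distinct event time.
#' @export
breslow_baseline <- function(cohort, lp) {
  cohort <- validate_cohort(cohort)
  lp <- as.numeric(lp)
  if (length(lp) != nrow(cohort) || any(!is.finite(lp))) {
    abort("`lp` must be finite with one value per patient")
  }
  ev <- event_indicator(cohort)
  if (sum(ev) == 0) abort("no events: baseline hazard is unidentifiable")
  ord <- order(cohort$time_months)
  t_sorted <- cohort$time_months[ord]
  w_sorted <- exp(lp[ord])
  # risk-set sums: subjects with time >= t, i.e. reverse cumulative sums
  rev_cumsum <- rev(cumsum(rev(w_sorted)))
  ev_times <- sort(unique(cohort$time_months[ev == 1]))
  idx <- findInterval(ev_times, t_sorted, left.open = TRUE) + 1L
  denom <- rev_cumsum[idx]
  if (any(denom <= 0)) abort("empty risk set at an event time")
  d <- vapply(ev_times, function(t) sum(ev == 1 & cohort$time_months == t),
              numeric(1))
  out <- tibble::tibble(time = ev_times, n_event = d,
                        increment = d / denom,
                        cumhaz = cumsum(d / denom))
  class(out) <- c("vpm_baseline_hazard", class(out))
  out
}

#' Convert a Breslow estimate to a baseline survival step function
#'
#' `S0(t) = exp(-H0(t))`, right-continuous on `[0, domain]`.
#'
#' @param bh A [breslow_baseline()] result.
#' @param domain Upper end of the evaluable domain, months.
#' @return A [baseline_step()] `vpm_baseline`.
#' @export
baseline_to_survival <- function(bh, domain = 24) {
  stopifnot(inherits(bh, "vpm_baseline_hazard"))
  baseline_step(bh$time, exp(-bh$cumhaz), domain = domain)
}
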