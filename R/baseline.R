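#' Baseline survival functions
#'
#' The baseline survival \eqn{S_0(t)} of a Cox-type risk model can be
#' represented either as a piecewise-constant hazard (segments with a
#' hazard per month, the natural form for simulation presets) or as a
#' right-continuous step function of `(time, survival)` pairs (the natural
#' form of a Breslow-recalibrated baseline). Both evaluate on `[0, domain]`
#' months, default 24.
#'
#' @param breakpoints Increasing right endpoints of the hazard segments,
#'   months; the last one is the domain end.
#' @param hazards Hazard per month on each segment; same length as
#'   `breakpoints`, all `>= 0`.
#' @return A `vpm_baseline` object.
#' @examples
#' b <- baseline_piecewise(c(12, 24), c(0.004, 0.005))
#' baseline_survival(b, c(0, 12, 24))
#' @export
baseline_piecewise <- function(breakpoints, hazards) {
  if (length(breakpoints) != length(hazards) || length(hazards) == 0) {
    abort("`breakpoints` and `hazards` must be non-empty and equal length")
  }
  if (any(diff(c(0, breakpoints)) <= 0)) abort("`breakpoints` must be increasing and positive")
  if (any(hazards < 0)) abort("hazards must be >= 0")
  structure(list(type = "piecewise", breakpoints = as.numeric(breakpoints),
                 hazards = as.numeric(hazards),
                 domain = max(breakpoints)),
            class = "vpm_baseline")
}

#' @rdname baseline_piecewise
#' @param times Increasing step times (months) at which survival drops.
#' @param survival Survival value from each step time on; non-increasing,
#'   in (0, 1].
#' @param domain Upper end of the evaluable domain, months.
#' @export
baseline_step <- function(times, survival, domain = 24) {
  if (length(times) != length(survival)) abort("`times`/`survival` length mismatch")
  if (length(times) > 0) {
    if (any(diff(times) <= 0)) abort("step `times` must be strictly increasing")
    if (any(times < 0)) abort("step times must be >= 0")
    if (any(diff(survival) > 1e-12)) abort("baseline survival must be non-increasing")
    if (any(survival <= 0) || any(survival > 1)) abort("baseline survival must be in (0, 1]")
  }
  structure(list(type = "step", times = as.numeric(times),
                 survival = as.numeric(survival),
                 domain = max(domain, times)),
            class = "vpm_baseline")
}

#' Evaluate a baseline survival or cumulative hazard
#'
#' @param baseline A `vpm_baseline`.
#' @param t Times in months, all within `[0, domain]`.
#' @return `baseline_survival()`: \eqn{S_0(t)}; `baseline_cumhaz()`:
#'   \eqn{H_0(t) = -\log S_0(t)}. Both right-continuous in `t`.
#' @export
baseline_survival <- function(baseline, t) {
  exp(-baseline_cumhaz(baseline, t))
}

#' @rdname baseline_survival
#' @export
baseline_cumhaz <- function(baseline, t) {
  stopifnot(inherits(baseline, "vpm_baseline"))
  if (any(t < 0 | t > baseline$domain + 1e-9)) {
    abort(sprintf("t must lie in [0, %g] months", baseline$domain))
  }
  if (baseline$type == "piecewise") {
    starts <- c(0, utils::head(baseline$breakpoints, -1))
    # time spent in each segment, per evaluation point
    vapply(t, function(ti) {
      sum(baseline$hazards * pmax(0, pmin(ti, baseline$breakpoints) - starts))
    }, numeric(1))
  } else {
    if (length(baseline$times) == 0) return(rep(0, length(t)))
    f <- stepfun(baseline$times, c(0, -log(baseline$survival)), right = FALSE)
    f(t)
  }
}

#' @export
print.vpm_baseline <- function(x, ...) {
  if (x$type == "piecewise") {
    cat(sprintf("<vpm_baseline> piecewise-constant hazard on [0, %g] months\n", x$domain))
    print(tibble::tibble(segment_end = x$breakpoints, hazard_per_month = x$hazards))
  } else {
    cat(sprintf("<vpm_baseline> step function, %d steps on [0, %g] months\n",
                length(x$times), x$domain))
    if (length(x$times) > 0) {
      cat(sprintf("  S0(%g) = %.5f\n", x$domain, min(x$survival)))
    }
  }
  invisible(x)
}
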