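#' Define a VPM-type risk model
#'
#' The Vienna Prediction Model (VPM) is a Cox-model based score for the
#' recurrence risk of unprovoked venous thromboembolism. Its linear
#' predictor is
#' \deqn{lp = \beta_{male}[male] + \beta_{prox}[proximal DVT] +
#'   \beta_{PE}[pulmonary embolism] + \beta_{log2D} \log_2(D\textrm{-dimer})}
#' with isolated distal DVT and female sex as reference levels and D-dimer
#' in ng/mL. Predicted cumulative recurrence risk at time \eqn{t} is
#' \eqn{1 - S_0(t)^{\exp(lp)}}, and the nomogram points score is the affine
#' map `points_intercept + points_slope * lp`. Patients at or below
#' `points_threshold` points (default 180, corresponding to a 1-year
#' predicted risk of `risk_threshold_1y`) are classified low risk.
#'
#' The constructor enforces the internal consistency of the two thresholds:
#' the predicted 12-month risk at the linear predictor whose points equal
#' `points_threshold` must equal `risk_threshold_1y` (within `1e-6`). Pass
#' `risk_threshold_1y = NULL` to have it derived from the points threshold
#' and the baseline, which is what [recalibrate_baseline()] does after
#' replacing the baseline.
#'
#' The package default weights and baseline (used when arguments are left
#' at their defaults, and shipped in
#' `inst/extdata/vpm_default_synthetic.yaml`) are a synthetic stand-in:
#' the numeric constants of the originally published VPM are not
#' redistributed here, so the defaults are plausible-magnitude weights with
#' the published effect directions, with the points map anchored so that
#' 180 points correspond exactly to a 5.5% 1-year risk. Supply your own
#' [read_vpm_definition()] config to score against a specific published
#' weight set.
#'
#' @param beta_male Log-hazard weight for male sex.
#' @param beta_proximal Log-hazard weight for proximal DVT (vs distal).
#' @param beta_pe Log-hazard weight for pulmonary embolism (vs distal).
#' @param beta_log2_ddimer Log-hazard weight per doubling of D-dimer.
#' @param baseline A [baseline_piecewise()] or [baseline_step()] object.
#' @param points_intercept,points_slope Affine map from linear predictor to
#'   nomogram points; `points_slope > 0`. `points_intercept = NULL` anchors
#'   the map so the points/risk thresholds agree exactly.
#' @param points_threshold Low-risk gate on the points scale (default 180;
#'   points strictly above it are high risk).
#' @param risk_threshold_1y 1-year predicted risk at the gate; `NULL`
#'   derives it from the other fields.
#' @param label Free-text model label recorded in outputs.
#' @return A `vpm_definition` object.
#' @examples
#' m <- vpm_definition()
#' predicted_risk(m, lp = 3, t = 12)
#' @export
vpm_definition <- function(beta_male = 0.6,
                           beta_proximal = 0.5,
                           beta_pe = 0.6,
                           beta_log2_ddimer = 0.25,
                           baseline = baseline_piecewise(c(12, 24),
                                                         c(2.3e-4, 2.3e-4)),
                           points_slope = 60,
                           points_intercept = NULL,
                           points_threshold = 180,
                           risk_threshold_1y = 0.055,
                           label = "synthetic-default") {
  stopifnot(inherits(baseline, "vpm_baseline"))
  assert_scalar_number(points_slope, "points_slope")
  if (points_slope <= 0) abort("`points_slope` must be > 0")
  for (nm in c("beta_male", "beta_proximal", "beta_pe", "beta_log2_ddimer")) {
    assert_scalar_number(get(nm), nm)
  }
  if (is.null(points_intercept)) {
    if (is.null(risk_threshold_1y)) {
      abort("one of `points_intercept`, `risk_threshold_1y` must be given")
    }
    # anchor: points_threshold points <=> risk_threshold_1y at 12 months
    lp_star <- log(-log1p(-risk_threshold_1y) / baseline_cumhaz(baseline, 12))
    points_intercept <- points_threshold - points_slope * lp_star
  }
  model <- structure(list(
    beta_male = beta_male, beta_proximal = beta_proximal, beta_pe = beta_pe,
    beta_log2_ddimer = beta_log2_ddimer, baseline = baseline,
    points_intercept = points_intercept, points_slope = points_slope,
    points_threshold = points_threshold,
    risk_threshold_1y = risk_threshold_1y, label = label
  ), class = "vpm_definition")
  lp_star <- (points_threshold - points_intercept) / points_slope
  risk_at_gate <- predicted_risk(model, lp_star, 12)
  if (is.null(risk_threshold_1y)) {
    model$risk_threshold_1y <- risk_at_gate
  } else if (abs(risk_at_gate - risk_threshold_1y) > 1e-6) {
    abort(sprintf(paste0(
      "inconsistent thresholds: predicted 12-month risk at %g points is ",
      "%.6f, not risk_threshold_1y = %.6f"),
      points_threshold, risk_at_gate, risk_threshold_1y))
  }
  model
}

#' @export
print.vpm_definition <- function(x, ...) {
  cat(sprintf("<vpm_definition> %s\n", x$label))
  cat(sprintf("  weights: male %.4g, proximal DVT %.4g, PE %.4g, log2 D-dimer %.4g\n",
              x$beta_male, x$beta_proximal, x$beta_pe, x$beta_log2_ddimer))
  cat(sprintf("  points = %.4g + %.4g * lp; low-risk gate: <= %g points (1y risk %.4g)\n",
              x$points_intercept, x$points_slope, x$points_threshold,
              x$risk_threshold_1y))
  cat(sprintf("  baseline: %s, S0(12) = %.5f, S0(%g) = %.5f\n", x$baseline$type,
              baseline_survival(x$baseline, 12), x$baseline$domain,
              baseline_survival(x$baseline, x$baseline$domain)))
  invisible(x)
}

#' Linear predictor of a VPM-type model
#'
#' @param cohort A cohort tibble (see [cohort-format]).
#' @param model A [vpm_definition()].
#' @return Numeric vector, one linear predictor per patient.
#' @export
vpm_linear_predictor <- function(cohort, model) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(model, "vpm_definition"))
  model$beta_male * (cohort$sex == "male") +
    model$beta_proximal * (cohort$site == "proximal_dvt") +
    model$beta_pe * (cohort$site == "pulmonary_embolism") +
    model$beta_log2_ddimer * log2(cohort$ddimer_ng_ml)
}

#' Nomogram points for a linear predictor
#'
#' @param model A [vpm_definition()].
#' @param lp Linear predictor value(s).
#' @return `points_intercept + points_slope * lp`, strictly increasing in
#'   `lp`.
#' @export
points_score <- function(model, lp) {
  stopifnot(inherits(model, "vpm_definition"))
  model$points_intercept + model$points_slope * lp
}

#' Predicted cumulative recurrence risk
#'
#' \eqn{1 - S_0(t)^{\exp(lp)}}; non-decreasing in both `t` and `lp`, zero
#' at `t = 0`.
#'
#' @param model A [vpm_definition()].
#' @param lp Linear predictor value(s).
#' @param t Horizon(s) in months within the baseline domain.
#' @return Probabilities, recycled over `lp`/`t` in the usual way.
#' @export
predicted_risk <- function(model, lp, t) {
  stopifnot(inherits(model, "vpm_definition"))
  -expm1(-baseline_cumhaz(model$baseline, t) * exp(lp))
}

#' Score a cohort against a VPM-type model
#'
#' Adds per-patient linear predictor, points, 1- and 2-year predicted
#' risks, and the low/high risk classification. The boundary belongs to
#' the low-risk class: a patient at exactly `points_threshold` points is
#' low risk.
#'
#' @param cohort A cohort tibble.
#' @param model A [vpm_definition()].
#' @return The cohort with columns `lp`, `points`, `risk_1y`, `risk_2y`,
#'   `risk_class` appended.
#' @examples
#' coh <- generate_study_like(seed = 1, n = 50)
#' vpm_score(coh, vpm_definition())
#' @export
vpm_score <- function(cohort, model) {
  cohort <- validate_cohort(cohort)
  lp <- vpm_linear_predictor(cohort, model)
  horizon2 <- min(24, model$baseline$domain)
  dplyr::mutate(
    cohort,
    lp = lp,
    points = points_score(model, lp),
    risk_1y = predicted_risk(model, lp, 12),
    risk_2y = predicted_risk(model, lp, horizon2),
    risk_class = dplyr::if_else(.data$points > model$points_threshold,
                                "high", "low")
  )
}

#' Predicted-risk surface over D-dimer
#'
#' Evaluates the model's predicted cumulative recurrence risk at a horizon
#' on a D-dimer grid for every sex-by-site stratum, the data behind a
#' risk-surface figure.
#'
#' @param model A [vpm_definition()].
#' @param ddimer Positive D-dimer grid, ng/mL.
#' @param horizon Months.
#' @return A tibble (class `vpm_risk_surface`) with one row per
#'   sex x site x grid point; see [autoplot.vpm_risk_surface()].
#' @export
risk_surface <- function(model, ddimer = c(100, 200, 300, 500, 750, 1000),
                         horizon = 24) {
  stopifnot(inherits(model, "vpm_definition"))
  if (length(ddimer) == 0 || any(ddimer <= 0)) abort("`ddimer` must be positive")
  grid <- tidyr::expand_grid(
    sex = cohort_levels$sex,
    site = cohort_levels$site,
    ddimer_ng_ml = sort(as.numeric(ddimer))
  )
  lp <- model$beta_male * (grid$sex == "male") +
    model$beta_proximal * (grid$site == "proximal_dvt") +
    model$beta_pe * (grid$site == "pulmonary_embolism") +
    model$beta_log2_ddimer * log2(grid$ddimer_ng_ml)
  out <- dplyr::mutate(grid, lp = lp,
                       risk = predicted_risk(model, lp, horizon),
                       horizon = horizon)
  class(out) <- c("vpm_risk_surface", class(out))
  out
}

#' Plot a predicted-risk surface
#'
#' @param object A [risk_surface()] result.
#' @param ... Unused.
#' @return A ggplot: risk vs D-dimer (log axis), one line per site,
#'   faceted by sex.
#' @export
autoplot.vpm_risk_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ddimer_ng_ml, y = .data$risk,
                                       colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "D-dimer (ng/mL)", y = sprintf("Predicted %g-month risk",
                                                     object$horizon[1]),
                  colour = "Index VTE site") +
    ggplot2::theme_minimal()
}

#' Read / write a VPM model definition config
#'
#' The config is YAML with the fields of [vpm_definition()]; the baseline
#' is given either as `{breakpoints, hazards}` (piecewise-constant hazard
#' per month) or `{times, survival}` (step function).
#'
#' @param path Path to a YAML config.
#' @return `read_vpm_definition()`: a `vpm_definition`;
#'   `write_vpm_definition()`: `path`, invisibly.
#' @export
read_vpm_definition <- function(path) {
  if (!file.exists(path)) abort(sprintf("model config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  b <- cfg$baseline
  baseline <- if (!is.null(b$breakpoints)) {
    baseline_piecewise(unlist(b$breakpoints), unlist(b$hazards))
  } else {
    baseline_step(unlist(b$times), unlist(b$survival),
                  domain = b$domain %||% 24)
  }
  vpm_definition(
    beta_male = cfg$beta_male, beta_proximal = cfg$beta_proximal,
    beta_pe = cfg$beta_pe, beta_log2_ddimer = cfg$beta_log2_ddimer,
    baseline = baseline,
    points_slope = cfg$points_slope,
    points_intercept = cfg$points_intercept,
    points_threshold = cfg$points_threshold %||% 180,
    risk_threshold_1y = cfg$risk_threshold_1y,
    label = cfg$label %||% basename(path)
  )
}

#' @rdname read_vpm_definition
#' @param model A `vpm_definition`.
#' @export
write_vpm_definition <- function(model, path) {
  stopifnot(inherits(model, "vpm_definition"))
  b <- model$baseline
  baseline <- if (b$type == "piecewise") {
    list(breakpoints = b$breakpoints, hazards = b$hazards)
  } else {
    list(times = b$times, survival = b$survival, domain = b$domain)
  }
  yaml::write_yaml(list(
    label = model$label,
    beta_male = model$beta_male, beta_proximal = model$beta_proximal,
    beta_pe = model$beta_pe, beta_log2_ddimer = model$beta_log2_ddimer,
    points_intercept = model$points_intercept,
    points_slope = model$points_slope,
    points_threshold = model$points_threshold,
    risk_threshold_1y = model$risk_threshold_1y,
    baseline = baseline
  ), path, precision = 15)
  invisible(path)
}
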