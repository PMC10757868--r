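#' Descriptive baseline summary of a cohort
#'
#' Medians and interquartile ranges (type-7 quantiles) for continuous
#' variables, counts and integer percentages (rounded half-up) for
#' categorical variables — the layout of a baseline-characteristics table.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `variable`, `level`, `n`, `pct`,
#'   `median`, `q1`, `q3`; categorical rows fill `n`/`pct`, continuous
#'   rows fill the quantile columns.
#' @export
describe_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  cat_row <- function(variable, values, levels) {
    counts <- as.integer(table(factor(values, levels = levels)))
    pcts <- pct_of(counts, n)
    tibble::tibble(variable = variable,
                   level = levels,
                   n = counts, pct = pcts,
                   median = NA_real_, q1 = NA_real_, q3 = NA_real_)
  }
  cont_row <- function(variable, values) {
    q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(variable = variable, level = NA_character_,
                   n = NA_integer_, pct = NA_real_,
                   median = q[2], q1 = q[1], q3 = q[3])
  }
  dplyr::bind_rows(
    cat_row("sex", cohort$sex, cohort_levels$sex),
    cat_row("site", cohort$site, cohort_levels$site),
    cont_row("ddimer_ng_ml", cohort$ddimer_ng_ml),
    cont_row("time_months", cohort$time_months),
    cat_row("event", cohort$event, cohort_levels$event),
    cat_row("end_reason", cohort$end_reason, cohort_levels$end_reason)
  )
}

#' Run the full study pipeline on a cohort
#'
#' End-to-end orchestration of the analysis stages on one low-risk
#' cohort: descriptive summary, per-patient scoring, Kaplan-Meier
#' estimation with 12- and 24-month cumulative incidences and their
#' threshold z-tests (against 8% at 1 year and 13% at 2 years),
#' second-year actuarial and person-time rates, external validation
#' (calibration slope, O/E, Uno's c, grouped calibration) and baseline
#' recalibration with bootstrap internal validation. Deterministic given
#' `seed`; all stage seeds derive from it.
#'
#' @param cohort A cohort tibble (or a path readable by [read_cohort()]).
#' @param model A [vpm_definition()] (or a path readable by
#'   [read_vpm_definition()]).
#' @param horizon Months.
#' @param null_1y,null_2y Threshold risks for the z-tests.
#' @param n_boot Bootstrap resamples for validation/recalibration.
#' @param seed Top-level RNG seed.
#' @return A `vpm_study_report` list with elements `table1`, `scored`,
#'   `curve`, `incidence`, `threshold_tests`, `rates`, `validation`,
#'   `recalibration`, `provenance`.
#' @export
run_study_pipeline <- function(cohort, model = vpm_definition(), horizon = 24,
                               null_1y = 0.08, null_2y = 0.13,
                               n_boot = 1000, seed = 1L) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(model)) model <- read_vpm_definition(model)
  cohort <- validate_cohort(cohort)
  seed <- as.integer(seed)
  if (sum(event_indicator(cohort)) == 0) {
    abort("estimation stage: cohort has zero recurrence events")
  }
  scored <- vpm_score(cohort, model)
  curve <- kaplan_meier(cohort)
  t_eval <- c(12, min(horizon, max(curve$time)))
  incidence <- dplyr::bind_rows(purrr::map(t_eval, ~cumulative_incidence_at(curve, .x)))
  tests <- dplyr::bind_rows(
    threshold_z_test(incidence$estimate[1], incidence$se[1], null_1y),
    threshold_z_test(incidence$estimate[2], incidence$se[2], null_2y)
  )
  rates <- dplyr::bind_rows(
    dplyr::mutate(person_time_rate(cohort, 0, 12), interval = "year1"),
    dplyr::mutate(person_time_rate(cohort, 12, 24), interval = "year2")
  )
  validation <- validate_model(cohort, model, horizon = horizon,
                               n_boot = n_boot, seed = seed + 101L)
  recalibration <- recalibrate(cohort, model, horizon = horizon,
                               n_boot = n_boot, seed = seed + 202L)
  structure(list(
    table1 = describe_cohort(cohort),
    scored = scored,
    curve = curve,
    incidence = incidence,
    threshold_tests = tests,
    actuarial_year2 = actuarial_interval_rate(cohort, 12, 24),
    rates = rates,
    validation = validation,
    recalibration = recalibration,
    provenance = list(seed = seed, n_boot = n_boot, horizon = horizon,
                      model_label = model$label, n = nrow(cohort),
                      package_version = as.character(utils::packageVersion("vpmrecal")))
  ), class = "vpm_study_report")
}

#' @export
print.vpm_study_report <- function(x, ...) {
  cat(sprintf("<vpm_study_report> n = %d patients, seed = %d\n",
              x$provenance$n, x$provenance$seed))
  cat(sprintf("  cumulative incidence: %.1f%% at 12 mo (95%% CI %.1f-%.1f), %.1f%% at %g mo (95%% CI %.1f-%.1f)\n",
              100 * x$incidence$estimate[1], 100 * x$incidence$ci_low[1],
              100 * x$incidence$ci_high[1], 100 * x$incidence$estimate[2],
              x$incidence$time[2], 100 * x$incidence$ci_low[2],
              100 * x$incidence$ci_high[2]))
  cat(sprintf("  threshold tests: p = %.3g (vs %.0f%%), p = %.3g (vs %.0f%%)\n",
              x$threshold_tests$p_one_sided[1], 100 * x$threshold_tests$null_value[1],
              x$threshold_tests$p_one_sided[2], 100 * x$threshold_tests$null_value[2]))
  print(x$validation)
  print(x$recalibration)
  invisible(x)
}
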