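# data generated from the default model's own baseline and weights
model_generated_cohort <- function(n, seed, hazard_scale = 1,
                                   male_shift = 0) {
  base_model <- vpm_definition()
  gen_model <- vpm_definition(beta_male = base_model$beta_male + male_shift,
                              points_intercept = base_model$points_intercept,
                              risk_threshold_1y = NULL)
  h <- 2.3e-4 * hazard_scale
  config <- sim_config(n = n, model = gen_model,
                       hazard_breakpoints = c(12, 24), hazards = c(h, h))
  coh <- sample_covariates(config, seed = seed) |>
    sample_event_times(config, seed = seed + 1L) |>
    apply_censoring(config, seed = seed + 2L)
  list(cohort = coh, scored_model = base_model)
}

test_that("lack-of-fit deltas are near zero on model-generated data", {
  sim <- model_generated_cohort(2000, seed = 83)
  out <- lack_of_fit_test(sim$cohort, sim$scored_model)
  expect_true(all(abs(out$deltas$estimate) < 3 * out$deltas$std_error))
  expect_true(out$p_value > 0 && out$p_value <= 1)
  expect_equal(out$df, 4)
})

test_that("lack-of-fit recovers an injected male-weight shift", {
  sim <- model_generated_cohort(2000, seed = 89, male_shift = 0.7)
  out <- lack_of_fit_test(sim$cohort, sim$scored_model)
  d_male <- out$deltas[out$deltas$term == "male", ]
  expect_lt(abs(d_male$estimate - 0.7), 3 * d_male$std_error)
  expect_lt(out$p_value, 0.05)
})

test_that("few events per parameter triggers a warning, not silence", {
  sim <- model_generated_cohort(800, seed = 97)
  few <- sim$cohort
  keep_ev <- which(few$event == "recurrence")[1:3]
  few <- dplyr::bind_rows(few[keep_ev, ],
                          few[few$event == "censored", ][1:200, ])
  expect_warning(lack_of_fit_test(few, sim$scored_model), "events")
})

test_that("baseline recalibration leaves weights bit-identical and fixes O/E at 1", {
  sim <- model_generated_cohort(700, seed = 101, hazard_scale = 1.6)
  recal <- recalibrate_baseline(sim$cohort, sim$scored_model)
  expect_identical(recal$beta_male, sim$scored_model$beta_male)
  expect_identical(recal$beta_proximal, sim$scored_model$beta_proximal)
  expect_identical(recal$beta_pe, sim$scored_model$beta_pe)
  expect_identical(recal$beta_log2_ddimer, sim$scored_model$beta_log2_ddimer)
  expect_equal(oe_ratio(sim$cohort, recal, 24)$oe, 1, tolerance = 1e-12)
  # idempotent in O/E: recalibrating the recalibrated model changes nothing
  recal2 <- recalibrate_baseline(sim$cohort, recal)
  expect_equal(oe_ratio(sim$cohort, recal2, 24)$oe, 1, tolerance = 1e-12)
  expect_equal(baseline_survival(recal2$baseline, 0:24),
               baseline_survival(recal$baseline, 0:24), tolerance = 1e-12)
  # the points gate stays primary: the derived 1-year risk gate matches it
  lp_gate <- (recal$points_threshold - recal$points_intercept) / recal$points_slope
  expect_equal(predicted_risk(recal, lp_gate, 12), recal$risk_threshold_1y)
})

test_that("recalibration recovers a 1.6x hazard inflation", {
  sim <- model_generated_cohort(6000, seed = 103, hazard_scale = 1.6)
  recal <- recalibrate_baseline(sim$cohort, sim$scored_model)
  orig_risk <- 1 - baseline_survival(sim$scored_model$baseline, 24)
  recal_risk <- 1 - baseline_survival(recal$baseline, 24)
  # at small baseline risks the cumulative risk scales ~ with the hazard
  expect_equal(recal_risk / orig_risk, 1.6, tolerance = 0.15)
})

test_that("bootstrap baseline bands are reproducible, contain the point
           estimate, and shrink with cohort size", {
  sim <- model_generated_cohort(400, seed = 107)
  b1 <- bootstrap_baseline_ci(sim$cohort, sim$scored_model, n_boot = 120,
                              seed = 11)
  b2 <- bootstrap_baseline_ci(sim$cohort, sim$scored_model, n_boot = 120,
                              seed = 11)
  expect_equal(b1, b2)
  expect_true(all(b1$ci_low <= b1$estimate + 1e-12))
  expect_true(all(b1$ci_high >= b1$estimate - 1e-12))

  widths <- vapply(c(250, 1000, 4000), function(n) {
    sim_n <- model_generated_cohort(n, seed = 109)
    b <- bootstrap_baseline_ci(sim_n$cohort, sim_n$scored_model,
                               n_boot = 120, seed = 13)
    mean(b$ci_high[b$time >= 12] - b$ci_low[b$time >= 12])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # ~1/sqrt(n) scaling: 16x the patients should shrink widths about 4x
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.5)
})

test_that("optimism-corrected O/E is near 1 on model-generated data and
           seed-reproducible", {
  sim <- model_generated_cohort(2000, seed = 113)
  out <- optimism_corrected_oe(sim$cohort, sim$scored_model, horizon = 24,
                               n_boot = 150, seed = 17)
  expect_equal(out$oe_apparent, 1, tolerance = 1e-12)
  expect_lt(abs(out$oe_corrected - 1), 0.15)
  expect_true(out$ci_low < 1 && 1 < out$ci_high)
  out2 <- optimism_corrected_oe(sim$cohort, sim$scored_model, horizon = 24,
                                n_boot = 150, seed = 17)
  expect_equal(out, out2)

  none <- make_cohort(c(5, 10, 20), 0)
  expect_error(optimism_corrected_oe(none, sim$scored_model, horizon = 24,
                                     n_boot = 10, seed = 1), "zero events")
})

test_that("the assembled recalibration report is internally consistent", {
  sim <- model_generated_cohort(600, seed = 127)
  rep <- recalibrate(sim$cohort, sim$scored_model, n_boot = 100, seed = 19)
  g <- glance(rep)
  expect_equal(g$n_boot, 100)
  expect_equal(oe_ratio(sim$cohort, rep$model, 24)$oe, 1, tolerance = 1e-12)
  expect_true(g$lack_of_fit_p > 0 && g$lack_of_fit_p <= 1)
  expect_s3_class(autoplot(rep$baseline_ci), "ggplot")
})
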