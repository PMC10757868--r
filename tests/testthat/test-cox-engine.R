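test_that("Cox coefficient matches the brute-force partial-likelihood maximizer", {
  # two groups, four subjects, no ties: grid/optimize oracle on the hand
  # written partial likelihood
  coh <- make_cohort(c(1, 3, 2, 4), c(1, 1, 1, 0))
  coh$group <- c(0, 0, 1, 1)
  fit <- fit_cox(coh, covariates = "group")
  oracle <- optimize(
    function(b) log_partial_likelihood(b, coh$time_months,
                                       c(1, 1, 1, 0), coh$group),
    interval = c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coefficients), oracle$maximum, tolerance = 1e-6)
  expect_equal(fit$log_partial_likelihood, oracle$objective, tolerance = 1e-9)
  # partial likelihood at the maximizer beats nearby perturbations
  for (d in c(-0.1, -0.01, 0.01, 0.1)) {
    expect_lt(log_partial_likelihood(fit$coefficients + d, coh$time_months,
                                     c(1, 1, 1, 0), coh$group),
              fit$log_partial_likelihood)
  }
})

test_that("Cox fit recovers generating coefficients within 3 SE", {
  model <- vpm_definition(beta_male = 0.7, beta_proximal = -0.3, beta_pe = 0,
                          beta_log2_ddimer = 0,
                          baseline = baseline_piecewise(c(12, 24),
                                                        c(0.01, 0.01)),
                          points_intercept = 0, risk_threshold_1y = NULL)
  config <- const_hazard_config(5000, 0.01, model = model)
  coh <- sample_covariates(config, seed = 31) |>
    sample_event_times(config, seed = 32) |>
    apply_censoring(config, seed = 33)
  coh$male <- as.numeric(coh$sex == "male")
  coh$proximal <- as.numeric(coh$site == "proximal_dvt")
  fit <- fit_cox(coh, covariates = c("male", "proximal"))
  td <- tidy(fit)
  expect_true(fit$converged)
  expect_lt(abs(td$estimate[td$term == "male"] - 0.7),
            3 * td$std_error[td$term == "male"])
  expect_lt(abs(td$estimate[td$term == "proximal"] - (-0.3)),
            3 * td$std_error[td$term == "proximal"])
})

test_that("degenerate designs are rejected rather than silently fitted", {
  coh <- make_cohort(c(1, 2, 3, 4), c(1, 1, 0, 0))
  coh$same <- 1
  expect_error(fit_cox(coh, covariates = "same"), "constant")
  coh$a <- c(1, 2, 3, 4)
  coh$b <- 2 * coh$a
  expect_error(fit_cox(coh, covariates = c("a", "b")), "collinear")
  none <- make_cohort(c(1, 2), c(0, 0))
  none$x <- c(0, 1)
  expect_error(fit_cox(none, covariates = "x"), "zero events")
})

test_that("likelihood-ratio test follows the chi-square reference", {
  coh <- make_cohort(c(1, 2, 3, 4), c(1, 1, 1, 0))
  coh$x <- c(0, 1, 0, 1)
  full <- fit_cox(coh, covariates = "x")
  expect_equal(likelihood_ratio_test(full, full, df = 1)$p_value, 1)
  # hand example: log-likelihoods -10 vs -12.5 with df 4
  fake_full <- structure(list(log_partial_likelihood = -10), class = "vpm_coxfit")
  fake_red <- structure(list(log_partial_likelihood = -12.5), class = "vpm_coxfit")
  out <- likelihood_ratio_test(fake_full, fake_red, df = 4)
  expect_equal(out$statistic, 5)
  expect_equal(out$p_value, pchisq(5, 4, lower.tail = FALSE))
  expect_equal(round(out$p_value, 4), 0.2873)
  expect_error(likelihood_ratio_test(fake_red, fake_full, df = 4), "nested")
})

test_that("Breslow baseline reduces to Nelson-Aalen at zero linear predictor", {
  coh <- make_cohort(c(2, 5, 5, 9, 13), c(1, 1, 1, 1, 0))
  bh <- breslow_baseline(coh, rep(0, 5))
  # Nelson-Aalen: d/n at each event time
  expect_equal(bh$time, c(2, 5, 9))
  expect_equal(bh$increment, c(1 / 5, 2 / 4, 1 / 2))
  expect_equal(bh$cumhaz, cumsum(c(1 / 5, 2 / 4, 1 / 2)))
})

test_that("Breslow increments match hand risk-set arithmetic and the
           martingale identity holds to machine precision", {
  coh <- make_cohort(c(1, 2, 3), c(1, 1, 0))
  lp <- c(0, log(2), 0)
  bh <- breslow_baseline(coh, lp)
  expect_equal(bh$increment[1], 1 / (1 + 2 + 1)) # risk set {1,2,3}
  expect_equal(bh$increment[2], 1 / (2 + 1))     # risk set {2,3}
  # sum_i H0(t_i) exp(lp_i) = number of events, exactly
  H <- stepfun(bh$time, c(0, bh$cumhaz))(coh$time_months)
  expect_equal(sum(H * exp(lp)), 2, tolerance = 1e-14)

  coh2 <- random_cohort(150, 17)
  lp2 <- withr::with_seed(18, rnorm(150, 0, 0.8))
  bh2 <- breslow_baseline(coh2, lp2)
  H2 <- stepfun(bh2$time, c(0, bh2$cumhaz))(coh2$time_months)
  expect_equal(sum(H2 * exp(lp2)), sum(coh2$event == "recurrence"),
               tolerance = 1e-12)
})

test_that("baseline-hazard to survival conversion is an exact inverse", {
  coh <- random_cohort(60, 23)
  bh <- breslow_baseline(coh, rep(0.3, 60))
  s0 <- baseline_to_survival(bh)
  expect_equal(-log(baseline_survival(s0, bh$time)), bh$cumhaz,
               tolerance = 1e-12)
  # single increment: survival steps down once
  one <- make_cohort(c(6, 10), c(1, 0))
  s1 <- baseline_to_survival(breslow_baseline(one, c(0, 0)))
  expect_equal(baseline_survival(s1, c(0, 5.999)), c(1, 1))
  expect_equal(baseline_survival(s1, c(6, 20)), rep(exp(-1 / 2), 2))
})

test_that("offset enters with fixed weight one", {
  coh <- random_cohort(200, 29)
  lp <- withr::with_seed(30, rnorm(200))
  # follow-up is independent of lp, so refitting the offset's own values
  # as a covariate must cancel it: coefficient near -1 only if the offset
  # really enters with weight fixed at 1
  coh$extra <- lp
  fit <- fit_cox(coh, covariates = "extra", offset = lp)
  td <- tidy(fit)
  expect_lt(abs(td$estimate - (-1)), 3 * td$std_error)
  # offset-only fit returns the partial likelihood with no free parameters
  null_fit <- fit_cox(coh, covariates = character(), offset = lp)
  expect_length(null_fit$coefficients, 0)
  expect_true(is.finite(null_fit$log_partial_likelihood))
})
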