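# build a minimal valid cohort from follow-up data; covariates default to
# the reference patient (female, distal DVT) unless supplied
make_cohort <- function(time, event, sex = "female", site = "distal_dvt",
                        ddimer = 100) {
  n <- length(time)
  is_event <- rep_len(event, n) == 1
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    sex = rep_len(sex, n),
    site = rep_len(site, n),
    ddimer_ng_ml = rep_len(ddimer, n),
    time_months = time,
    event = ifelse(is_event, "recurrence", "censored"),
    end_reason = ifelse(is_event, "recurrence", "lost")
  )
}

# random valid cohort for property-style round-trip checks
random_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    ev <- rbinom(n, 1, 0.3)
    coh <- make_cohort(
      time = round(runif(n, 0, 24), 3),
      event = ev,
      sex = sample(c("male", "female"), n, replace = TRUE),
      site = sample(c("distal_dvt", "proximal_dvt", "pulmonary_embolism"),
                    n, replace = TRUE),
      ddimer = sample(seq(60, 2000, by = 10), n, replace = TRUE)
    )
    coh$end_reason[ev == 0] <- sample(
      c("completed_24mo", "restarted_anticoagulation", "death_other",
        "withdrew", "lost"), sum(ev == 0), replace = TRUE)
    coh
  })
}

# log partial likelihood (no ties assumed) for the brute-force Cox oracle
log_partial_likelihood <- function(beta, time, event, x) {
  eta <- as.numeric(as.matrix(x) %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    ll <- ll + eta[i] - log(sum(exp(eta[time >= time[i]])))
  }
  ll
}

# a simple constant-hazard generating config built on a given model
const_hazard_config <- function(n, hazard, model = vpm_definition(),
                                dropout = 0, admin = 24) {
  sim_config(n = n, model = model, hazard_breakpoints = c(12, 24),
             hazards = c(hazard, hazard), admin_censor_months = admin,
             dropout_rate_per_month = dropout)
}
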