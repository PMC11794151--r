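# Kaplan-Meier, log-rank, Cox, cumulative risk, landmark rule and the
# adjusted logistic odds ratio.

surv_frame <- function(entry, exit, event, group, ...) {
  data.frame(person_id = seq_along(exit), time_entry = entry,
             time_exit = exit, event = event, group = group, ...)
}

test_that("landmark rule drops events within three months of entry", {
  expect_false(landmark_filter(60.1, 60.0))
  expect_true(landmark_filter(60.3, 60.0))
  expect_true(landmark_filter(NA, 60.0))      # no event, nothing to drop
  expect_identical(landmark_filter(numeric(0), numeric(0)), logical(0))
  expect_true(landmark_filter(60.25, 60.0))   # boundary kept (>= entry+0.25)

  coh <- data.frame(person_id = 1:3, carrier_status = "HETEROZYGOTE",
                    deceased = FALSE, age_entry = 60,
                    age_last_followup_or_death = 70,
                    has_HM = c(TRUE, TRUE, FALSE),
                    has_MM = FALSE,
                    age_first_HM = c(60.1, 62, NA), age_first_MM = NA_real_)
  s <- survival_input(coh, "HM")
  expect_identical(s$event, c(FALSE, TRUE, FALSE))
  # the landmark-dropped subject stays at risk to last follow-up
  expect_identical(s$time_exit, c(70, 62, 70))
})

test_that("KM without censoring equals the empirical survival fraction", {
  set.seed(2)
  times <- sort(rexp(150, 0.1))
  s <- surv_frame(0, times, TRUE, "carrier")
  fit <- km_estimate(s, by_group = FALSE)
  for (t0 in quantile(times, c(0.1, 0.5, 0.9))) {
    expect_equal(summary(fit, times = t0)$surv, mean(times > t0),
                 tolerance = 1e-10)
  }
  # all censored: the curve never drops
  fit2 <- km_estimate(surv_frame(0, times, FALSE, "carrier"),
                      by_group = FALSE)
  expect_true(all(fit2$surv == 1))
  expect_error(km_estimate(surv_frame(0, times, TRUE, "x")[0, ]), "empty")
})

test_that("log-rank test uses shared risk sets, with and without truncation", {
  set.seed(3)
  n <- 300
  g <- rep(c("carrier", "control"), each = n / 2)
  haz <- ifelse(g == "carrier", 0.2, 0.05)
  s <- surv_frame(0, rexp(n, haz), TRUE, g)
  lr <- logrank_test(s)
  expect_identical(lr$method, "survdiff")
  expect_lt(lr$p_value, 1e-6)
  # agreement with survdiff directly
  sd_ <- survival::survdiff(survival::Surv(time_exit, event) ~ group,
                            data = s)
  expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-10)
  # delayed entry switches to the Cox score test
  entry <- runif(n, 0, 1)
  s2 <- surv_frame(entry, entry + rexp(n, haz), TRUE, g)
  lr2 <- logrank_test(s2)
  expect_identical(lr2$method, "cox score")
  expect_lt(lr2$p_value, 1e-6)
  expect_error(logrank_test(s[s$group == "carrier", ]), "two non-empty")
})

test_that("Cox partial likelihood maximum matches the algebraic solution", {
  # three subjects, one binary covariate, all events at distinct times:
  # the score equation reduces to 2u^2 = 1 with u = exp(beta)
  s <- surv_frame(0, c(1, 2, 3), TRUE, c("carrier", "control", "carrier"))
  fit <- survival::coxph(survival::Surv(time_exit, event) ~
                           I(group == "carrier"), data = s,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), -log(2) / 2, tolerance = 1e-6)
  est <- cox_hr(s, covariates = character(0))
  expect_equal(log(est$estimate), -log(2) / 2, tolerance = 1e-6)
})

test_that("Cox recovers a planted hazard ratio under left truncation", {
  cfg <- sim_config(n_individuals = 20000, carrier_prevalence = 0.05,
                    carrier_log_hr = log(1.8))
  sim <- simulate_cohort(cfg, seed = 11)
  coh <- suppressMessages(build_analysis_cohort(
    sim$phenotypes, sim$diagnoses, triage_variants(sim$calls)))
  est <- cox_hr(survival_input(coh, "death"))
  expect_true(est$ci_low <= 1.8 && 1.8 <= est$ci_high)
  expect_lt(abs(log(est$estimate) - log(1.8)), 0.35)
  # a constant covariate is dropped with a warning, fit proceeds
  s <- survival_input(coh, "death")
  s$constant <- 1
  expect_warning(est2 <- cox_hr(s, covariates = c("male", "constant")),
                 "no variation")
  expect_true(is.finite(est2$estimate))
  # no events at all is a clean diagnostic
  s0 <- s; s0$event <- FALSE
  expect_error(cox_hr(s0), "no events")
})

test_that("cumulative risk is 1 - S by decade, monotone, NA past follow-up", {
  # S(80) = 0.75 by construction: 25 of 100 die before 80
  exit <- c(rep(70, 25), rep(85, 75))
  s <- surv_frame(0, exit, c(rep(TRUE, 25), rep(FALSE, 75)), "carrier")
  cr <- cumulative_risk_by_decade(s)
  expect_equal(cr$risk_percent[cr$age == 80], 25, tolerance = 1e-10)
  expect_identical(cr$risk_percent[cr$age == 0], 0)
  expect_identical(cr$ci_low[cr$age == 0], 0)   # zero-risk rows are 0 (0-0)
  expect_true(all(is.na(cr$risk_percent[cr$age == 90])))
  r <- cr$risk_percent[!is.na(cr$risk_percent)]
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 100))
  # no events anywhere: flat zero
  s0 <- surv_frame(0, rep(85, 50), FALSE, "carrier")
  cr0 <- cumulative_risk_by_decade(s0)
  ok <- !is.na(cr0$risk_percent)
  expect_true(all(cr0$risk_percent[ok] == 0))
})

test_that("cumulative risk matches the closed-form piecewise-exponential risk", {
  cfg <- sim_config(n_individuals = 20000, carrier_prevalence = 0,
                    dvus_fraction = 0, benign_fraction = 0,
                    followup_years = 40)
  sim <- simulate_cohort(cfg, seed = 5)
  coh <- suppressMessages(build_analysis_cohort(
    sim$phenotypes, sim$diagnoses, triage_variants(sim$calls)))
  s <- survival_input(coh, "death")
  cr <- cumulative_risk_by_decade(s, ages = c(60, 70, 80))
  # analytic risk conditional on being alive at the cohort's youngest
  # entry age a0: 1 - exp(-(H(t) - H(a0)))
  a0 <- min(s$time_entry)
  H <- function(t) piecewise_cumhaz(t, cfg$mortality_breaks,
                                    cfg$mortality_rates)
  truth <- 100 * (1 - exp(-(H(c(60, 70, 80)) - H(a0))))
  expect_equal(cr$risk_percent, truth, tolerance = 0.12)
})

test_that("logistic OR with no covariates equals the crude 2x2 OR", {
  set.seed(13)
  n <- 4000
  carrier <- rbinom(n, 1, 0.1) == 1
  y <- rbinom(n, 1, ifelse(carrier, 0.3, 0.1)) == 1
  coh <- data.frame(person_id = 1:n,
                    carrier_status = ifelse(carrier, "HETEROZYGOTE",
                                            "CONTROL"),
                    has_HM = y, has_MM = FALSE)
  est <- adjusted_or_logistic(coh, "HM", covariates = character(0))
  a <- sum(carrier & y); b <- sum(carrier & !y)
  c_ <- sum(!carrier & y); d <- sum(!carrier & !y)
  crude <- crude_or_2x2(a, b, c_, d)
  expect_equal(est$estimate, crude$estimate, tolerance = 1e-6)
})

test_that("logistic OR recovers a planted carrier log-OR with covariates", {
  cfg <- sim_config(n_individuals = 50000, outcome_model = "logistic",
                    carrier_log_or = log(4.6))
  sim <- simulate_cohort(cfg, seed = 17)
  coh <- suppressMessages(build_analysis_cohort(
    sim$phenotypes, sim$diagnoses, triage_variants(sim$calls)))
  est <- adjusted_or_logistic(coh, "HM")
  expect_true(est$ci_low <= 4.6 && 4.6 <= est$ci_high)
  # QC-excluded rows never enter the fit
  expect_identical(est$n_denominator,
                   sum(coh$carrier_status != "EXCLUDED"))
})

test_that("degenerate logistic fits are reported, not crashed", {
  coh <- data.frame(person_id = 1:40,
                    carrier_status = rep(c("HETEROZYGOTE", "CONTROL"),
                                         each = 20),
                    has_HM = rep(c(TRUE, FALSE), each = 20),
                    has_MM = FALSE)
  expect_warning(est <- adjusted_or_logistic(coh, "HM",
                                             covariates = character(0)),
                 "separation")
  expect_true(is.na(est$estimate))
  coh$has_HM <- FALSE
  expect_error(adjusted_or_logistic(coh, "HM", covariates = character(0)),
               "at least one event")
})
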