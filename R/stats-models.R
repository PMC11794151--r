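## Model-based estimates: adjusted logistic odds ratios, Kaplan-Meier /
## log-rank, Cox hazard ratios and decade-binned cumulative risk. The
## survival clock is age with left truncation at entry age by default
## (delayed entry: each subject joins the risk set only at the age first
## observed), with an enrollment-time clock available via `clock`.

#' Landmark filter for time-to-event outcomes
#'
#' Drops malignancy events recorded within a landmark period after the
#' first EHR encounter, so prevalent disease present at entry does not
#' masquerade as incident disease. Applies only to time-to-event
#' analyses, never to prevalence or penetrance counts.
#'
#' @param onset_age Event onset ages (years), `NA` for no event.
#' @param entry_age Entry (first-encounter) ages, recycled.
#' @param months Landmark length; default 3 months = 0.25 years.
#' @return Logical vector: `TRUE` where the event is kept. `NA` onsets
#'   (no event) are kept.
#' @export
#' @examples
#' landmark_filter(60.1, 60.0)  # FALSE: within 3 months of entry
#' landmark_filter(60.3, 60.0)  # TRUE
landmark_filter <- function(onset_age, entry_age, months = 3) {
  is.na(onset_age) | onset_age >= entry_age + months / 12
}

#' Build survival-analysis input from a cohort
#'
#' Converts cohort rows into (entry, exit, event, group) counting-process
#' form. QC-excluded rows are dropped, as are rows with no follow-up
#' (exit not after entry). For malignancy outcomes the landmark rule
#' removes events within `landmark_months` of entry and follow-up for an
#' event stops at onset.
#'
#' @param cohort A [build_analysis_cohort()] result (or any data frame
#'   with the same columns).
#' @param outcome `"death"`, `"HM"` or `"MM"`.
#' @param clock `"age"` (left-truncated at entry age, the default) or
#'   `"followup"` (time since entry).
#' @param landmark_months Landmark period for malignancy outcomes.
#' @return Data frame: `person_id`, `time_entry`, `time_exit`, `event`
#'   (logical), `group` (`"carrier"`/`"control"`), covariate columns.
#' @export
survival_input <- function(cohort, outcome = c("death", "HM", "MM"),
                           clock = c("age", "followup"),
                           landmark_months = 3) {
  outcome <- match.arg(outcome)
  clock <- match.arg(clock)
  d <- cohort[cohort$carrier_status != "EXCLUDED", , drop = FALSE]
  if (outcome == "death") {
    event <- as.logical(d$deceased)
    exit <- d$age_last_followup_or_death
  } else {
    onset <- if (outcome == "HM") d$age_first_HM else d$age_first_MM
    has <- if (outcome == "HM") d$has_HM else d$has_MM
    keep_event <- landmark_filter(onset, d$age_entry, landmark_months)
    event <- has & keep_event & !is.na(onset)
    exit <- ifelse(event, onset, d$age_last_followup_or_death)
  }
  out <- data.frame(
    person_id = d$person_id,
    time_entry = d$age_entry,
    time_exit = exit,
    event = event,
    group = ifelse(d$carrier_status == "HETEROZYGOTE", "carrier", "control"),
    stringsAsFactors = FALSE)
  for (v in intersect(c("male", "bmi", "smoking_ever", "race", "age_entry"),
                      names(d)))
    out[[v]] <- d[[v]]
  if (clock == "followup") {
    out$time_exit <- out$time_exit - out$time_entry
    out$time_entry <- 0
  }
  ok <- is.finite(out$time_exit) & out$time_exit > out$time_entry
  n_drop <- sum(!ok)
  if (n_drop) message(n_drop, " row(s) without positive follow-up dropped")
  out[ok, , drop = FALSE]
}

surv_formula <- function(covariates = NULL) {
  rhs <- paste(c("group", covariates), collapse = " + ")
  stats::as.formula(paste(
    "survival::Surv(time_entry, time_exit, event) ~", rhs))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator over the event time scale with delayed-entry
#' risk sets and Greenwood variance; a thin wrapper around
#' [survival::survfit()] with log-log confidence intervals.
#'
#' @param surv A [survival_input()] data frame.
#' @param by_group Fit separate curves per `group` (default) or pooled.
#' @return A `survfit` object.
#' @export
km_estimate <- function(surv, by_group = TRUE) {
  if (!nrow(surv)) stop("empty survival input")
  f <- if (by_group && length(unique(surv$group)) > 1) surv_formula()
       else stats::as.formula(
         "survival::Surv(time_entry, time_exit, event) ~ 1")
  survival::survfit(f, data = surv, conf.type = "log-log")
}

#' Log-rank test between two groups
#'
#' Observed-versus-expected comparison over the shared risk sets. With a
#' common entry time this is [survival::survdiff()]; with delayed entry
#' (age clock) it is the score test of the corresponding Cox model,
#' which is the log-rank generalization for counting-process data.
#'
#' @param surv A [survival_input()] data frame with two groups.
#' @return List with `chisq`, `df`, `p_value`, `method`.
#' @export
logrank_test <- function(surv) {
  groups <- unique(surv$group)
  if (length(groups) != 2 || any(table(surv$group) == 0))
    stop("log-rank test needs two non-empty groups")
  if (length(unique(surv$time_entry)) == 1L) {
    sd_ <- survival::survdiff(
      survival::Surv(time_exit - time_entry, event) ~ group, data = surv)
    list(chisq = sd_$chisq, df = 1L,
         p_value = stats::pchisq(sd_$chisq, 1, lower.tail = FALSE),
         method = "survdiff")
  } else {
    fit <- survival::coxph(surv_formula(), data = surv, ties = "breslow")
    sc <- summary(fit)$sctest
    list(chisq = unname(sc["test"]), df = as.integer(sc["df"]),
         p_value = unname(sc["pvalue"]), method = "cox score")
  }
}

drop_degenerate <- function(data, covariates) {
  keep <- covariates[vapply(covariates, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    length(unique(x)) > 1
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped))
    warning("covariate(s) with no variation dropped: ",
            paste(dropped, collapse = ", "))
  keep
}

#' Adjusted odds ratio by logistic regression
#'
#' Maximum-likelihood logistic fit of outcome on carrier status plus
#' covariates, on complete cases; QC-excluded rows never enter. The
#' carrier odds ratio is `exp` of its coefficient with a Wald 95\% CI.
#' Covariates constant in the analysis data are dropped with a warning;
#' complete separation is reported as non-estimable rather than a crash.
#'
#' @param cohort A [build_analysis_cohort()] result.
#' @param outcome `"HM"` or `"MM"` (uses `has_HM`/`has_MM`).
#' @param covariates Adjustment set; defaults to age, sex, BMI and
#'   smoking. Use `character(0)` for a crude model.
#' @return A [gmmp_estimate()] for the carrier odds ratio, with the full
#'   per-predictor table in `attr(, "predictors")` and the `glm` fit in
#'   `attr(, "fit")`.
#' @export
adjusted_or_logistic <- function(cohort, outcome = c("HM", "MM"),
                                 covariates = c("age_current", "male",
                                                "bmi", "smoking_ever")) {
  outcome <- match.arg(outcome)
  d <- as.data.frame(cohort)
  d <- d[d$carrier_status != "EXCLUDED", , drop = FALSE]
  d$carrier <- d$carrier_status == "HETEROZYGOTE"
  d$y <- if (outcome == "HM") d$has_HM else d$has_MM
  cols <- c("y", "carrier", covariates)
  d <- d[stats::complete.cases(d[cols]), cols, drop = FALSE]
  if (sum(d$y) == 0 || sum(d$y) == nrow(d))
    stop("need at least one event and one non-event")
  covariates <- drop_degenerate(d, covariates)
  f <- stats::as.formula(paste(
    "y ~ carrier", if (length(covariates))
      paste("+", paste(covariates, collapse = " + ")) else ""))
  fit <- stats::glm(f, family = stats::binomial(), data = d)
  sm <- summary(fit)$coefficients
  separated <- !fit$converged ||
    any(abs(sm[, "Estimate"]) > 15 | sm[, "Std. Error"] > 15)
  z <- stats::qnorm(0.975)
  idx <- "carrierTRUE"
  if (separated) {
    warning("possible complete separation: carrier OR non-estimable")
    est <- gmmp_estimate(NA_real_, NA_real_, NA_real_, NA_real_,
                         n_numerator = sum(d$carrier),
                         n_denominator = nrow(d),
                         label = paste("adjusted OR,", outcome))
  } else {
    b <- sm[idx, "Estimate"]; se <- sm[idx, "Std. Error"]
    est <- gmmp_estimate(exp(b), exp(b - z * se), exp(b + z * se),
                         sm[idx, "Pr(>|z|)"],
                         n_numerator = sum(d$carrier),
                         n_denominator = nrow(d),
                         label = paste("adjusted OR,", outcome))
  }
  tab <- data.frame(predictor = rownames(sm), or = exp(sm[, "Estimate"]),
                    ci_low = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
                    ci_high = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
                    p_value = sm[, "Pr(>|z|)"], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(est, "predictors") <- tab
  attr(est, "fit") <- fit
  est
}

#' Adjusted hazard ratio by Cox regression
#'
#' Partial-likelihood fit with Breslow tie handling on left-truncated
#' (delayed entry) risk sets. The carrier hazard ratio is `exp` of its
#' coefficient with a Wald 95\% CI.
#'
#' @param surv A [survival_input()] data frame.
#' @param covariates Adjustment set drawn from the covariate columns of
#'   `surv`; constant covariates are dropped with a warning.
#' @return A [gmmp_estimate()] for the carrier hazard ratio, with the
#'   `coxph` fit in `attr(, "fit")`.
#' @export
cox_hr <- function(surv, covariates = c("male", "bmi", "smoking_ever")) {
  covariates <- intersect(covariates, names(surv))
  d <- surv[stats::complete.cases(
    surv[c("time_entry", "time_exit", "event", "group", covariates)]), ,
    drop = FALSE]
  if (!sum(d$event)) stop("no events: hazard ratio non-estimable")
  covariates <- drop_degenerate(d, covariates)
  d$group <- factor(d$group, levels = c("control", "carrier"))
  fit <- survival::coxph(surv_formula(covariates), data = d,
                         ties = "breslow")
  if (any(is.na(stats::coef(fit))))
    stop("Cox model did not converge to finite coefficients")
  sm <- summary(fit)$coefficients
  idx <- grep("^groupcarrier$", rownames(sm))
  b <- sm[idx, "coef"]; se <- sm[idx, "se(coef)"]
  z <- stats::qnorm(0.975)
  est <- gmmp_estimate(exp(b), exp(b - z * se), exp(b + z * se),
                       sm[idx, "Pr(>|z|)"],
                       n_numerator = sum(d$group == "carrier"),
                       n_denominator = nrow(d),
                       label = "adjusted HR")
  attr(est, "fit") <- fit
  est
}

#' Cumulative risk by decade of age
#'
#' Tabulates `1 - S(age)` from the Kaplan-Meier estimator at ages 0,
#' 10, ..., 90, as percentages with log-log (Greenwood) confidence
#' intervals. Ages beyond observed follow-up are reported as missing;
#' ages with nobody yet at risk, or at risk but event-free, carry zero
#' risk with a degenerate (0, 0) interval.
#'
#' @param surv A [survival_input()] data frame, typically already
#'   restricted to one group (e.g. heterozygotes).
#' @param ages Evaluation ages.
#' @return Data frame: `age`, `risk_percent`, `ci_low`, `ci_high`,
#'   `n_risk`.
#' @export
cumulative_risk_by_decade <- function(surv, ages = seq(0, 90, 10)) {
  fit <- km_estimate(surv, by_group = FALSE)
  max_obs <- max(surv$time_exit)
  s <- summary(fit, times = pmin(ages, max_obs), extend = TRUE)
  risk <- 100 * (1 - s$surv)
  lo <- 100 * (1 - s$upper)
  hi <- 100 * (1 - s$lower)
  zero <- s$surv >= 1
  lo[zero] <- 0; hi[zero] <- 0
  beyond <- ages > max_obs
  risk[beyond] <- NA; lo[beyond] <- NA; hi[beyond] <- NA
  data.frame(age = ages, risk_percent = risk, ci_low = lo, ci_high = hi,
             n_risk = s$n.risk)
}
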