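## Synthetic-cohort generator. Emits annotated variant calls, phenotype
## and diagnosis tables with a known ground truth so the whole
## triage -> cohort -> estimation pipeline can be exercised and validated
## without access to restricted biobank data. Defaults emulate a
## population biobank carrying an eight-gene myeloid predisposition
## panel: carrier prevalence about 1 in 500, background lifetime
## hematological-malignancy frequency 2.5%, elevated per-gene carrier
## penetrance, and all-cause mortality following a piecewise-exponential
## age hazard with a carrier hazard ratio of 1.8.

#' Simulation configuration
#'
#' @param n_individuals Cohort size.
#' @param carrier_prevalence Probability of carrying a P/LP panel
#'   variant.
#' @param gene_freq Named relative frequencies of the carrier's gene;
#'   dominated by DDX41 as in real panels of these genes.
#' @param penetrance_carrier Named per-gene probability that a carrier
#'   ever develops a hematological malignancy.
#' @param penetrance_background Background HM probability for
#'   non-carriers.
#' @param mm_fraction_given_hm Probability an HM is specifically myeloid.
#' @param mortality_breaks,mortality_rates Piecewise-exponential
#'   all-cause mortality hazard: `mortality_rates[i]` (per year) applies
#'   from age `mortality_breaks[i]` to the next break; the last rate is
#'   open-ended.
#' @param carrier_log_hr Log hazard ratio multiplying the mortality
#'   hazard for carriers.
#' @param outcome_model `"penetrance"` assigns HM from the per-gene
#'   penetrances; `"logistic"` assigns it from a logistic model with a
#'   planted carrier log odds ratio (`carrier_log_or`) and mild covariate
#'   effects — the mode used for odds-ratio parameter-recovery
#'   experiments.
#' @param carrier_log_or Planted carrier log odds ratio (logistic mode).
#' @param sex_p_male,entry_age_mean,entry_age_sd,bmi_mean,bmi_sd,smoking_p
#'   Covariate distributions.
#' @param followup_years Administrative censoring after entry.
#' @param qc_noise Fraction of carrier calls emitted with an
#'   out-of-window VAF or low GQ (their carriers become QC-excluded).
#' @param dvus_fraction Fraction of individuals given a deleterious-VUS
#'   call.
#' @param benign_fraction Fraction of individuals given a call that
#'   triages to NOT_USED (benign, common, or unsupported VUS).
#' @param left_truncate `"conditional"` samples death conditional on
#'   survival to entry (a correctly left-truncated population, the
#'   default); `"cohort"` simulates mortality from birth and silently
#'   drops individuals dying before their entry age, reproducing the
#'   enrollment survivorship bias that depresses penetrance estimates
#'   for early-lethal genotypes.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10000,
                       carrier_prevalence = 1 / 500,
                       gene_freq = c(DDX41 = 0.70, SRP72 = 0.09,
                                     MECOM = 0.08, ANKRD26 = 0.05,
                                     CEBPA = 0.03, ETV6 = 0.02,
                                     RUNX1 = 0.02, GATA2 = 0.01),
                       penetrance_carrier = c(ANKRD26 = 0.02,
                                              CEBPA = 0.026, DDX41 = 0.04,
                                              ETV6 = 0.20, GATA2 = 0.25,
                                              MECOM = 0.02, RUNX1 = 0.33,
                                              SRP72 = 0.017),
                       penetrance_background = 0.025,
                       mm_fraction_given_hm = 0.25,
                       mortality_breaks = c(0, 40, 50, 60, 70, 80, 90),
                       mortality_rates = c(0.0005, 0.001, 0.003, 0.008,
                                           0.02, 0.06, 0.15),
                       carrier_log_hr = log(1.8),
                       outcome_model = c("penetrance", "logistic"),
                       carrier_log_or = log(4.6),
                       sex_p_male = 0.46,
                       entry_age_mean = 50, entry_age_sd = 15,
                       bmi_mean = 29, bmi_sd = 6,
                       smoking_p = 0.6,
                       followup_years = 15,
                       qc_noise = 0.05,
                       dvus_fraction = 0.017,
                       benign_fraction = 0.02,
                       left_truncate = c("conditional", "cohort")) {
  outcome_model <- match.arg(outcome_model)
  left_truncate <- match.arg(left_truncate)
  probs <- c(carrier_prevalence, penetrance_background,
             mm_fraction_given_hm, sex_p_male, smoking_p, qc_noise,
             dvus_fraction, benign_fraction, penetrance_carrier)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  stopifnot(n_individuals > 0,
            length(mortality_breaks) == length(mortality_rates),
            all(diff(mortality_breaks) > 0), all(mortality_rates > 0),
            abs(sum(gene_freq) - 1) < 1e-8)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Piecewise-exponential cumulative hazard
#'
#' Closed-form cumulative hazard of the generator's mortality model,
#' used both by the sampler and as an analytic oracle: under it the true
#' cumulative risk by age `t` is `1 - exp(-hr * piecewise_cumhaz(t, ...))`.
#'
#' @param t Ages.
#' @param breaks,rates Hazard segments, see [sim_config()].
#' @return Cumulative hazard at each `t`.
#' @export
piecewise_cumhaz <- function(t, breaks, rates) {
  vapply(t, function(ti) {
    upper <- c(breaks[-1], Inf)
    sum(rates * pmax(0, pmin(ti, upper) - breaks))
  }, numeric(1))
}

## inverse of the cumulative hazard beyond age a0: smallest t with
## H(t) - H(a0) = e. A uniform per-subject multiplier rescales the whole
## hazard, so inversion happens on the baseline scale with e / mult;
## memorylessness makes conditional (delayed-entry) sampling exact.
piecewise_exp_sample <- function(a0, e, breaks, rates, mult = 1) {
  h_at <- c(0, cumsum(rates[-length(rates)] * diff(breaks)))
  h0 <- h_at[findInterval(a0, breaks)] +
    rates[findInterval(a0, breaks)] * (a0 - breaks[findInterval(a0, breaks)])
  target <- h0 + e / mult
  i <- findInterval(target, h_at)
  breaks[i] + (target - h_at[i]) / rates[i]
}

plp_variant_pool <- function(gene, n_carriers) {
  n_var <- max(1L, as.integer(round(n_carriers / 4)))
  sprintf("%s_plp_%03d", tolower(gene), seq_len(n_var))
}

#' Simulate annotated variant calls
#'
#' Emits one call table covering every triage branch: carriers receive a
#' P/LP-consistent call (ClinVar/InterVar P or LP, heterozygous VAF, high
#' GQ, rare in every subpopulation); a `qc_noise` fraction of those calls
#' violate the VAF or GQ gate instead; `dvus_fraction` of the remaining
#' individuals get a VUS with three or more deleteriousness votes or two
#' splice votes; `benign_fraction` get calls that triage to NOT_USED
#' (benign assertion, common allele, or evidence-free VUS).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seed and config give identical
#'   tables.
#' @return List with `calls` (variant call table for
#'   [triage_variants()]) and `truth` (per-person `true_carrier`,
#'   `true_gene`, `expected_status`).
#' @export
simulate_variants <- function(cfg, seed = 1) {
  set.seed(seed)
  n <- cfg$n_individuals
  ids <- sprintf("P%06d", seq_len(n))
  carrier <- stats::rbinom(n, 1, cfg$carrier_prevalence) == 1
  gene <- rep(NA_character_, n)
  gene[carrier] <- sample(names(cfg$gene_freq), sum(carrier), TRUE,
                          prob = cfg$gene_freq)

  call_rows <- list()
  plp_call <- function(pid, g, bad_qc) {
    m <- length(pid)
    pool <- plp_variant_pool(g, max(4, sum(gene == g, na.rm = TRUE)))
    vaf <- pmin(pmax(stats::rbeta(m, 60, 60), 0.36), 0.64)  # het window
    gq <- sample(60:99, m, TRUE)
    if (any(bad_qc)) {
      bad_vaf <- bad_qc & stats::runif(m) < 0.7
      bad_gq <- bad_qc & !bad_vaf
      nbv <- sum(bad_vaf)
      vaf[bad_vaf] <- ifelse(stats::runif(nbv) < 0.5,
                             stats::runif(nbv, 0.05, 0.30),
                             stats::runif(nbv, 0.70, 0.95))
      gq[bad_gq] <- sample(5:30, sum(bad_gq), TRUE)
    }
    data.frame(
      person_id = pid, gene = g,
      variant_id = sample(pool, length(pid), TRUE),
      consequence = sample(c("frameshift", "nonsense", "missense",
                             "splice_site"), length(pid), TRUE,
                           prob = c(0.5, 0.25, 0.2, 0.05)),
      clinvar = sample(c("P", "LP", "ABSENT"), length(pid), TRUE,
                       prob = c(0.35, 0.45, 0.2)),
      intervar = "LP",
      cadd = round(stats::runif(length(pid), 22, 45), 1),
      metasvm = "D", revel = round(stats::runif(length(pid), 0.5, 1), 3),
      bayesdel = "D", eigen = round(stats::runif(length(pid), 0, 1), 3),
      spidex_splice = FALSE, spliceai_splice = FALSE, hsf_splice = FALSE,
      vaf = round(vaf, 3), gq = gq,
      af_NFE = signif(stats::runif(length(pid), 0, 5e-4), 3),
      af_AFR = 0, af_EAS = 0,
      stringsAsFactors = FALSE)
  }

  if (any(carrier)) {
    bad <- stats::runif(sum(carrier)) < cfg$qc_noise
    rows <- do.call(rbind, lapply(unique(gene[carrier]), function(g) {
      sel <- which(carrier & gene == g)
      plp_call(ids[sel], g, bad[match(sel, which(carrier))])
    }))
    ## recompute which emitted calls actually fail QC (bad draws are
    ## forced out of window / low GQ above)
    call_rows$plp <- rows
  }

  non_carrier_ids <- ids[!carrier]
  n_dvus <- stats::rbinom(1, length(non_carrier_ids), cfg$dvus_fraction)
  dvus_ids <- sample(non_carrier_ids, n_dvus)
  if (n_dvus) {
    splice_route <- stats::runif(n_dvus) < 0.3
    call_rows$dvus <- data.frame(
      person_id = dvus_ids,
      gene = sample(names(cfg$gene_freq), n_dvus, TRUE, cfg$gene_freq),
      variant_id = sprintf("dvus_%04d", sample.int(2000, n_dvus, TRUE)),
      consequence = ifelse(splice_route, "splice_site", "missense"),
      clinvar = "VUS", intervar = "VUS",
      cadd = ifelse(splice_route, NA, round(stats::runif(n_dvus, 21, 35), 1)),
      metasvm = ifelse(splice_route, NA, "D"),
      revel = ifelse(splice_route, NA,
                     round(stats::runif(n_dvus, 0.51, 0.9), 3)),
      bayesdel = "T", eigen = -0.5,
      spidex_splice = splice_route, spliceai_splice = splice_route,
      hsf_splice = FALSE,
      vaf = round(stats::rbeta(n_dvus, 60, 60), 3),
      gq = sample(60:99, n_dvus, TRUE),
      af_NFE = signif(stats::runif(n_dvus, 0, 5e-4), 3),
      af_AFR = 0, af_EAS = 0,
      stringsAsFactors = FALSE)
    call_rows$dvus$vaf <- pmin(pmax(call_rows$dvus$vaf, 0.36), 0.64)
  }

  rest <- setdiff(non_carrier_ids, dvus_ids)
  n_ben <- stats::rbinom(1, length(rest), cfg$benign_fraction)
  ben_ids <- sample(rest, n_ben)
  if (n_ben) {
    kind <- sample(c("benign", "common", "weak_vus"), n_ben, TRUE)
    call_rows$benign <- data.frame(
      person_id = ben_ids,
      gene = sample(names(cfg$gene_freq), n_ben, TRUE, cfg$gene_freq),
      variant_id = sprintf("bg_%04d", sample.int(2000, n_ben, TRUE)),
      consequence = "missense",
      clinvar = ifelse(kind == "benign", "LB", "VUS"),
      intervar = ifelse(kind == "benign", "B", "VUS"),
      cadd = round(stats::runif(n_ben, 0, 19), 1),
      metasvm = "T", revel = round(stats::runif(n_ben, 0, 0.4), 3),
      bayesdel = "T", eigen = -1,
      spidex_splice = FALSE, spliceai_splice = FALSE, hsf_splice = FALSE,
      vaf = round(pmin(pmax(stats::rbeta(n_ben, 60, 60), 0.36), 0.64), 3),
      gq = sample(60:99, n_ben, TRUE),
      af_NFE = ifelse(kind == "common",
                      signif(stats::runif(n_ben, 0.02, 0.2), 3), 1e-4),
      af_AFR = 0, af_EAS = 0,
      stringsAsFactors = FALSE)
  }

  calls <- do.call(rbind, call_rows)
  if (is.null(calls))
    calls <- data.frame(
      person_id = character(), gene = character(),
      variant_id = character(), consequence = character(),
      clinvar = character(), intervar = character(), cadd = numeric(),
      metasvm = character(), revel = numeric(), bayesdel = character(),
      eigen = numeric(), spidex_splice = logical(),
      spliceai_splice = logical(), hsf_splice = logical(),
      vaf = numeric(), gq = numeric(), af_NFE = numeric(),
      af_AFR = numeric(), af_EAS = numeric(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  qc_fail_ids <- character(0)
  if (!is.null(call_rows$plp)) {
    qc <- genotype_qc(call_rows$plp$vaf, call_rows$plp$gq)
    qc_fail_ids <- unique(call_rows$plp$person_id[qc != "PASS"])
  }
  truth <- data.frame(person_id = ids, true_carrier = carrier,
                      true_gene = gene, stringsAsFactors = FALSE)
  truth$expected_status <- ifelse(
    truth$person_id %in% qc_fail_ids, "EXCLUDED",
    ifelse(carrier, "HETEROZYGOTE", "CONTROL"))
  list(calls = calls, truth = truth)
}

hm_group_codes <- list(
  AML = list(c("10", "C92.0"), c("10", "C92.9"), c("9", "205.0")),
  MDS = list(c("10", "D46.9"), c("10", "D46.2"), c("9", "238.72")),
  MPN = list(c("10", "D47.1"), c("10", "D45")),
  NHL = list(c("10", "C83.3"), c("10", "C82.0"), c("9", "202.8")),
  HL = list(c("10", "C81.9"), c("9", "201.9")),
  PCM = list(c("10", "C90.0"), c("9", "203.0")),
  ALL_CLL = list(c("10", "C91.1"), c("9", "204.1"))
)

#' Simulate phenotype and diagnosis tables
#'
#' Draws covariates, assigns hematological-malignancy outcomes (per-gene
#' carrier penetrance versus background rate, or a planted-log-OR
#' logistic model), simulates all-cause mortality from the
#' piecewise-exponential age hazard with the carrier hazard ratio, and
#' emits EHR-style diagnosis records: one to three ICD codes per true
#' event scattered within the five-year reconciliation window, an
#' occasional re-diagnosis more than five years later, and occasional
#' relapse flags.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_variants()].
#' @param seed Integer seed (an independent sub-stream: internally offset
#'   from the variant stream so the two tables are separately
#'   reproducible).
#' @return List with `phenotypes`, `diagnoses` and the augmented `truth`
#'   (outcome flags, onset and death ages).
#' @export
simulate_phenotypes <- function(cfg, truth, seed = 1) {
  set.seed(seed + 1000003L)
  n <- nrow(truth)
  male <- stats::rbinom(n, 1, cfg$sex_p_male) == 1
  entry <- rtruncnorm1(n, cfg$entry_age_mean, cfg$entry_age_sd, 18, 80)
  bmi <- round(stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 1)
  smoking <- stats::rbinom(n, 1, cfg$smoking_p) == 1
  race <- sample(c("White", "Black", "Asian", "Other"), n, TRUE,
                 prob = c(0.85, 0.07, 0.04, 0.04))
  carrier <- truth$true_carrier & truth$expected_status != "EXCLUDED"

  hr_mult <- ifelse(carrier, exp(cfg$carrier_log_hr), 1)
  e <- stats::rexp(n)
  death_age <- piecewise_exp_sample(
    if (cfg$left_truncate == "conditional") entry else rep(0, n),
    e, cfg$mortality_breaks, cfg$mortality_rates, hr_mult)
  keep <- rep(TRUE, n)
  if (cfg$left_truncate == "cohort") keep <- death_age > entry
  censor_age <- entry + cfg$followup_years
  deceased <- death_age <= censor_age
  age_last <- pmin(death_age, censor_age)

  if (cfg$outcome_model == "penetrance") {
    p_hm <- ifelse(carrier, cfg$penetrance_carrier[truth$true_gene],
                   cfg$penetrance_background)
    p_hm[is.na(p_hm)] <- cfg$penetrance_background
  } else {
    lp <- stats::qlogis(cfg$penetrance_background) +
      cfg$carrier_log_or * carrier +
      0.02 * (entry - cfg$entry_age_mean) + 0.2 * male +
      0.3 * smoking + 0.01 * (bmi - cfg$bmi_mean)
    p_hm <- stats::plogis(lp)
  }
  has_hm <- stats::rbinom(n, 1, p_hm) == 1
  is_mm <- has_hm & stats::rbinom(n, 1, cfg$mm_fraction_given_hm) == 1
  ## diagnoses are EHR records: an HM exists in the data only if recorded
  ## during the person's observed life, so onset is drawn within it
  onset <- rep(NA_real_, n)
  onset[has_hm] <- rtruncnorm1(sum(has_hm), 65, 12, 20,
                               pmax(21, age_last[has_hm]))

  group <- rep(NA_character_, n)
  group[is_mm] <- sample(c("AML", "MDS", "MPN"), sum(is_mm), TRUE,
                         prob = c(0.45, 0.4, 0.15))
  group[has_hm & !is_mm] <- sample(c("NHL", "HL", "PCM", "ALL_CLL"),
                                   sum(has_hm & !is_mm), TRUE,
                                   prob = c(0.5, 0.15, 0.15, 0.2))

  code_pool <- do.call(rbind, lapply(names(hm_group_codes), function(g) {
    m <- do.call(rbind, hm_group_codes[[g]])
    data.frame(group = g, icd_version = m[, 1], code = m[, 2],
               stringsAsFactors = FALSE)
  }))
  idx <- which(has_hm & keep)
  if (length(idx)) {
    k <- sample(1:3, length(idx), TRUE)
    first <- rep(FALSE, sum(k)); first[cumsum(k) - k + 1L] <- TRUE
    ev <- rep(idx, k)
    ages <- onset[ev] + stats::runif(length(ev), 0.1, 4)
    ages[first] <- onset[ev][first]
    rel <- !first & stats::runif(length(ev)) < 0.1
    # occasional re-diagnosis beyond the reconciliation window
    redo <- idx[stats::runif(length(idx)) < 0.03 &
                onset[idx] + 7 < age_last[idx]]
    ev <- c(ev, redo)
    ages <- c(ages, onset[redo] + stats::runif(length(redo), 5.5, 8))
    rel <- c(rel, rep(FALSE, length(redo)))
    pick <- vapply(group[ev], function(g) {
      rows <- which(code_pool$group == g)
      rows[sample.int(length(rows), 1)]
    }, integer(1))
    diagnoses <- data.frame(
      person_id = truth$person_id[ev],
      icd_version = code_pool$icd_version[pick],
      code = code_pool$code[pick],
      age_at_diagnosis = round(ages, 2),
      relapse_flag = rel, stringsAsFactors = FALSE)
    diagnoses <- diagnoses[order(match(diagnoses$person_id,
                                       truth$person_id)), ]
    rownames(diagnoses) <- NULL
  } else {
    diagnoses <- data.frame(
      person_id = character(), icd_version = character(),
      code = character(), age_at_diagnosis = numeric(),
      relapse_flag = logical(), stringsAsFactors = FALSE)
  }

  phenotypes <- data.frame(
    person_id = truth$person_id, sex = ifelse(male, "M", "F"),
    age_current = round(age_last, 2), age_entry = round(entry, 2),
    bmi = bmi, smoking_ever = smoking, race = race,
    deceased = deceased,
    age_last_followup_or_death = round(age_last, 2),
    stringsAsFactors = FALSE)[keep, , drop = FALSE]

  truth$true_has_HM <- has_hm
  truth$true_has_MM <- is_mm
  truth$true_onset_age <- onset
  truth$death_age <- death_age
  truth$entry_age <- entry
  truth <- truth[keep, , drop = FALSE]
  list(phenotypes = phenotypes, diagnoses = diagnoses, truth = truth)
}

#' Simulate a full cohort bundle
#'
#' Convenience wrapper running [simulate_variants()] then
#' [simulate_phenotypes()] with deterministically derived sub-streams.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `calls`, `phenotypes`, `diagnoses`, `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1) {
  v <- simulate_variants(cfg, seed)
  p <- simulate_phenotypes(cfg, v$truth, seed)
  list(calls = v$calls, phenotypes = p$phenotypes,
       diagnoses = p$diagnoses, truth = p$truth)
}

#' End-to-end parameter recovery report
#'
#' Runs the full pipeline (triage, cohort assembly, estimation) on
#' simulated cohorts across seeds and compares the estimates to the
#' generator's ground truth: prevalence and penetrance bias and CI
#' coverage, carrier OR and HR coverage.
#'
#' @param cfg A [sim_config()].
#' @param seeds Integer vector of seeds.
#' @param fit_or,fit_hr Also fit the logistic OR / Cox HR per seed
#'   (slower; both need enough events).
#' @return Data frame with one row per seed plus a `summary` attribute
#'   (mean estimates, coverage fractions).
#' @export
end_to_end_recovery <- function(cfg = sim_config(), seeds = 1:20,
                                fit_or = FALSE, fit_hr = FALSE) {
  rows <- lapply(seeds, function(s) {
    sim <- simulate_cohort(cfg, s)
    tri <- triage_variants(sim$calls)
    coh <- suppressMessages(
      build_analysis_cohort(sim$phenotypes, sim$diagnoses, tri))
    n_het <- sum(coh$carrier_status == "HETEROZYGOTE")
    n_eff <- sum(coh$carrier_status != "EXCLUDED")
    prev <- prevalence(n_het, n_eff)
    true_prev <- cfg$carrier_prevalence
    het <- coh[coh$carrier_status == "HETEROZYGOTE", ]
    pen <- if (n_het) penetrance(sum(het$has_HM), n_het) else NULL
    row <- data.frame(
      seed = s, n_het = n_het,
      prev_est = prev$estimate,
      prev_cover = prev$ci_low <= true_prev & true_prev <= prev$ci_high,
      pen_est = if (n_het) pen$estimate else NA_real_)
    if (fit_or) {
      or <- try(adjusted_or_logistic(coh, "HM"), silent = TRUE)
      row$or_est <- if (inherits(or, "try-error")) NA else or$estimate
      row$or_cover <- if (inherits(or, "try-error")) NA else
        or$ci_low <= exp(cfg$carrier_log_or) &
        exp(cfg$carrier_log_or) <= or$ci_high
    }
    if (fit_hr) {
      hr <- try(cox_hr(survival_input(coh, "death")), silent = TRUE)
      row$hr_est <- if (inherits(hr, "try-error")) NA else hr$estimate
      row$hr_cover <- if (inherits(hr, "try-error")) NA else
        hr$ci_low <= exp(cfg$carrier_log_hr) &
        exp(cfg$carrier_log_hr) <= hr$ci_high
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- colMeans(out[, -1, drop = FALSE], na.rm = TRUE)
  out
}
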