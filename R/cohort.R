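## Cohort assembly: ICD diagnosis streams -> reconciled malignancy
## events -> per-person analysis rows joined with triage results and
## phenotype covariates.

#' Reconcile raw ICD diagnosis records into malignancy events
#'
#' Repeated codes for the same malignancy group are chained into
#' episodes: sorted by age, a record joins the open episode if it falls
#' within `window_years` of the episode's most recent record or carries a
#' relapse flag; otherwise it opens a new event (a second, separate
#' malignancy of the same group). Different malignancy groups never
#' merge. Non-malignancy codes are dropped.
#'
#' @param records Data frame with columns `person_id`, `icd_version`,
#'   `code`, `age_at_diagnosis` and optional `relapse_flag`.
#' @param codemap See [default_codemap()].
#' @param window_years Same-malignancy reconciliation window (years).
#' @return Data frame of events: `person_id`, `malignancy_group`,
#'   `is_HM`, `is_MM`, `onset_age` (earliest record of the episode),
#'   `n_records`.
#' @export
reconcile_diagnoses <- function(records, codemap = default_codemap(),
                                window_years = 5) {
  stopifnot(all(c("person_id", "icd_version", "code",
                  "age_at_diagnosis") %in% names(records)))
  empty <- data.frame(person_id = character(), malignancy_group = character(),
                      is_HM = logical(), is_MM = logical(),
                      onset_age = numeric(), n_records = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  if (any(!is.finite(records$age_at_diagnosis) |
          records$age_at_diagnosis < 0))
    stop("age_at_diagnosis must be finite and non-negative")
  if (is.null(records$relapse_flag)) records$relapse_flag <- FALSE
  records$relapse_flag[is.na(records$relapse_flag)] <- FALSE

  m <- map_icd_codes(records$code, records$icd_version, codemap)
  keep <- !is.na(m$group)
  records <- cbind(records[keep, , drop = FALSE], m[keep, , drop = FALSE])
  if (!nrow(records)) return(empty)

  records <- records[order(records$person_id, records$group,
                           records$age_at_diagnosis), ]
  key <- paste(records$person_id, records$group, sep = "\r")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, ]
    episode <- cumsum(c(
      TRUE,
      (diff(r$age_at_diagnosis) > window_years) & !r$relapse_flag[-1]
    ))
    # gap measured to the most recent record of the open episode: diff()
    # on sorted ages is exactly that within an episode; a record > window
    # beyond its predecessor (and not a relapse) starts a new episode
    do.call(rbind, lapply(split(seq_along(idx), episode), function(i) {
      data.frame(person_id = r$person_id[1],
                 malignancy_group = r$group[1],
                 is_HM = r$is_HM[1], is_MM = r$is_MM[1],
                 onset_age = min(r$age_at_diagnosis[i]),
                 n_records = length(i), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$person_id, out$onset_age), ]
}

#' Carrier status from triage results
#'
#' Any passing P/LP call makes a person a heterozygote, even if the same
#' person has another call failing QC; a person whose only panel evidence
#' is a QC-failed call is excluded from the analyses entirely; everyone
#' else is a control.
#'
#' @param person_ids Vector of person identifiers to classify.
#' @param triage Output of [triage_variants()].
#' @return Character vector (`"HETEROZYGOTE"`, `"CONTROL"`, `"EXCLUDED"`)
#'   aligned with `person_ids`.
#' @export
assign_carrier_status <- function(person_ids, triage) {
  het <- unique(triage$person_id[triage$classification == "P_LP"])
  excl <- unique(triage$person_id[triage$classification == "EXCLUDED_QC"])
  status <- rep("CONTROL", length(person_ids))
  status[person_ids %in% excl] <- "EXCLUDED"
  status[person_ids %in% het] <- "HETEROZYGOTE"
  status
}

first_plp_gene <- function(person_ids, triage) {
  plp <- triage[triage$classification == "P_LP", , drop = FALSE]
  plp <- plp[!duplicated(plp$person_id), ]
  plp$gene[match(person_ids, plp$person_id)]
}

#' Assemble the per-person analysis cohort
#'
#' Joins the phenotype table, reconciled malignancy events and triage
#' results into one row per person, carrying carrier status, covariates,
#' HM/MM outcome flags with first-onset ages, and survival fields.
#' QC-excluded individuals are retained but flagged so downstream
#' analyses can drop them.
#'
#' @param phenotypes Data frame, one row per person: `person_id`, `sex`,
#'   `age_current`, `age_entry`, `bmi`, `smoking_ever`, `race`,
#'   `deceased`, `age_last_followup_or_death`. Missing covariates are
#'   kept as `NA` (complete-case deletion happens inside each model fit).
#' @param diagnoses Diagnosis records, see [reconcile_diagnoses()].
#' @param triage Output of [triage_variants()].
#' @param codemap See [default_codemap()].
#' @param window_years Reconciliation window passed through.
#' @return Data frame of class `gmmp_cohort`, one row per person, with a
#'   `counts` attribute summarizing status and outcome totals.
#' @export
build_analysis_cohort <- function(phenotypes, diagnoses, triage,
                                  codemap = default_codemap(),
                                  window_years = 5) {
  stopifnot(all(c("person_id", "age_entry",
                  "age_last_followup_or_death") %in% names(phenotypes)))
  if (anyDuplicated(phenotypes$person_id))
    stop("duplicate person_id in phenotype table")
  events <- reconcile_diagnoses(diagnoses, codemap, window_years)
  first_age <- function(flag) {
    ev <- events[flag, , drop = FALSE]
    if (!nrow(ev)) return(setNames(numeric(0), character(0)))
    tapply(ev$onset_age, ev$person_id, min)
  }
  hm_age <- first_age(events$is_HM)
  mm_age <- first_age(events$is_MM)

  out <- phenotypes
  if ("sex" %in% names(out) && !"male" %in% names(out))
    out$male <- toupper(substr(as.character(out$sex), 1, 1)) == "M"
  out$carrier_status <- assign_carrier_status(out$person_id, triage)
  out$gene <- first_plp_gene(out$person_id, triage)
  out$has_HM <- out$person_id %in% names(hm_age)
  out$has_MM <- out$person_id %in% names(mm_age)
  out$age_first_HM <- as.vector(hm_age[match(out$person_id, names(hm_age))])
  out$age_first_MM <- as.vector(mm_age[match(out$person_id, names(mm_age))])
  if (any(out$age_entry > out$age_last_followup_or_death, na.rm = TRUE))
    stop("age_entry after age_last_followup_or_death for some rows")

  counts <- list(
    n = nrow(out),
    by_status = table(out$carrier_status),
    n_HM = sum(out$has_HM), n_MM = sum(out$has_MM)
  )
  message(sprintf(
    "cohort: %d rows (%d heterozygote, %d control, %d excluded); %d HM, %d MM",
    counts$n, sum(out$carrier_status == "HETEROZYGOTE"),
    sum(out$carrier_status == "CONTROL"),
    sum(out$carrier_status == "EXCLUDED"), counts$n_HM, counts$n_MM))
  attr(out, "counts") <- counts
  class(out) <- c("gmmp_cohort", "data.frame")
  out
}
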