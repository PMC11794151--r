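## Orchestration and I/O: TSV/YAML readers, the triage -> cohort ->
## estimation pipeline, and rendering of results at printed precision.
## Raw (unrounded) values are serialized as JSON; formatting is a
## separate pass so printed tables stay auditable.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d
}

#' Read an annotated variant-call TSV
#'
#' Flat table with one row per (individual, variant) call; see
#' [triage_variants()] for the column contract. An optional column map
#' (named vector `internal_name = file_column`) renames non-standard
#' headers on ingest.
#'
#' @param path TSV path.
#' @param column_map Optional named character vector.
#' @return Data frame of calls.
#' @export
read_variant_calls <- function(path, column_map = NULL) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (internal in names(column_map)) {
      from <- column_map[[internal]]
      if (from %in% names(d)) names(d)[names(d) == from] <- internal
    }
  required <- c("person_id", "variant_id", "gene", "consequence",
                "clinvar", "intervar", "vaf", "gq")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("variant file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d
}

#' @rdname read_variant_calls
#' @export
read_phenotypes <- function(path) {
  read_tsv_checked(path, c("person_id", "age_entry",
                           "age_last_followup_or_death"), "phenotype")
}

#' @rdname read_variant_calls
#' @export
read_diagnoses <- function(path) {
  read_tsv_checked(path, c("person_id", "icd_version", "code",
                           "age_at_diagnosis"), "diagnosis")
}

#' Read a code map or triage configuration from YAML
#'
#' `read_codemap()` expects a list of entries with `icd_version`,
#' `prefix`, `group`, `is_HM`, `is_MM`; `read_triage_config()` accepts
#' any subset of the [triage_config()] arguments.
#'
#' @param path YAML path.
#' @return A codemap data frame / a `triage_config`.
#' @export
read_codemap <- function(path) {
  y <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(y, function(e)
    data.frame(icd_version = as.character(e$icd_version),
               prefix = normalize_icd(e$prefix), group = e$group,
               is_HM = isTRUE(e$is_HM), is_MM = isTRUE(e$is_MM),
               stringsAsFactors = FALSE)))
  if (any(out$is_MM & !out$is_HM))
    stop("codemap invalid: an MM entry must also be HM")
  out
}

#' @rdname read_codemap
#' @export
read_triage_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(triage_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown triage config key(s): ", paste(unknown, collapse = ", "))
  do.call(triage_config, y)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Triage -> cohort assembly -> estimation, with per-stage row-count
#' logging. The results bundle carries every estimate together with the
#' counts behind it, raw and unrounded, for audit; rendering to printed
#' precision is [render_tables()].
#'
#' @param calls Variant call table (or TSV path).
#' @param phenotypes Phenotype table (or TSV path).
#' @param diagnoses Diagnosis table (or TSV path).
#' @param triage_cfg A [triage_config()].
#' @param codemap A code map, see [default_codemap()].
#' @param covariates_or,covariates_hr Adjustment sets for the logistic
#'   and Cox models.
#' @param outdir Optional directory; when given, triage, cohort, burden,
#'   estimate and KM-coordinate files are written there.
#' @return A list of class `gmmp_results`: `triage`, `cohort`, `burden`,
#'   `estimates` (data frame of every [gmmp_estimate()]), `cumulative_risk`,
#'   `km` (curve coordinates), `demographics`.
#' @export
run_pipeline <- function(calls, phenotypes, diagnoses,
                         triage_cfg = triage_config(),
                         codemap = default_codemap(),
                         covariates_or = c("age_current", "male", "bmi",
                                           "smoking_ever"),
                         covariates_hr = c("male", "bmi", "smoking_ever"),
                         outdir = NULL) {
  if (is.character(calls)) calls <- read_variant_calls(calls)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (is.character(diagnoses)) diagnoses <- read_diagnoses(diagnoses)

  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message("stage ", name, ": ",
            if (is.data.frame(out)) paste(nrow(out), "rows") else "done")
    out
  }

  triage <- stage("triage", triage_variants(calls, triage_cfg))
  burden <- stage("gene_burden",
                  summarize_gene_burden(triage, triage_cfg$panel))
  cohort <- stage("cohort", suppressMessages(
    build_analysis_cohort(phenotypes, diagnoses, triage, codemap)))

  n_eff <- sum(cohort$carrier_status != "EXCLUDED")
  n_het <- sum(cohort$carrier_status == "HETEROZYGOTE")
  het <- cohort[cohort$carrier_status == "HETEROZYGOTE", , drop = FALSE]
  ests <- list(prevalence = prevalence(n_het, n_eff))
  n_dvus <- length(unique(
    triage$person_id[triage$classification == "dVUS"]))
  ests$dvus_frequency <- prevalence(n_dvus, n_eff, "dVUS frequency")
  if (n_het > 0) {
    ests$penetrance_HM <- penetrance(sum(het$has_HM), n_het,
                                     "penetrance, HM")
    ests$penetrance_MM <- penetrance(sum(het$has_MM), n_het,
                                     "penetrance, MM")
  }
  for (oc in c("HM", "MM")) {
    fit <- try(suppressWarnings(
      adjusted_or_logistic(cohort, oc, covariates_or)), silent = TRUE)
    if (!inherits(fit, "try-error"))
      ests[[paste0("or_", oc)]] <- fit
  }
  surv <- survival_input(cohort, "death")
  hr <- try(suppressWarnings(cox_hr(surv, covariates_hr)), silent = TRUE)
  if (!inherits(hr, "try-error")) ests$hr_death <- hr

  km <- if (length(unique(surv$group)) > 1) km_estimate(surv) else NULL
  km_coords <- if (!is.null(km)) {
    strata <- if (is.null(km$strata)) "all" else
      rep(sub("^group=", "", names(km$strata)), km$strata)
    data.frame(group = strata, age = km$time, surv = km$surv,
               ci_low = km$lower, ci_high = km$upper,
               n_risk = km$n.risk, stringsAsFactors = FALSE)
  } else NULL
  cum_risk <- if (sum(surv$group == "carrier") > 0) {
    cr <- try(cumulative_risk_by_decade(
      surv[surv$group == "carrier", , drop = FALSE]), silent = TRUE)
    if (inherits(cr, "try-error")) NULL else cr
  } else NULL
  demo <- try(compare_demographics(cohort), silent = TRUE)
  if (inherits(demo, "try-error")) demo <- NULL

  estimates <- do.call(rbind, lapply(names(ests), function(nm) {
    d <- as.data.frame(ests[[nm]])
    d$name <- nm
    d
  }))

  res <- structure(list(triage = triage, burden = burden, cohort = cohort,
                        estimates = estimates, estimate_objects = ests,
                        cumulative_risk = cum_risk, km = km_coords,
                        demographics = demo),
                   class = "gmmp_results")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(triage, file.path(outdir, "triage.tsv"))
    write_tsv(burden, file.path(outdir, "gene_burden.tsv"))
    write_tsv(as.data.frame(cohort), file.path(outdir, "cohort.tsv"))
    write_tsv(estimates, file.path(outdir, "estimates.tsv"))
    if (!is.null(km_coords))
      write_tsv(km_coords, file.path(outdir, "km_coordinates.tsv"))
    if (!is.null(cum_risk))
      write_tsv(cum_risk, file.path(outdir, "cumulative_risk.tsv"))
    jsonlite::write_json(
      lapply(ests, unclass), file.path(outdir, "estimates.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' Render result tables at printed precision
#'
#' Formats the estimates of a [run_pipeline()] bundle the way such
#' studies print them: penetrance as `1:N [p%]`, prevalence as
#' `p% (a-b)`, odds/hazard ratios as `v (a-b)` and cumulative risk per
#' decade as `r(a-b)` with zero-risk cells as `0 (0 to 0)` and
#' not-yet-observed decades as `-`. No arithmetic happens here besides
#' rounding.
#'
#' @param results A `gmmp_results` bundle.
#' @return List of character data frames: `estimates`, `cumulative_risk`.
#' @export
render_tables <- function(results) {
  ests <- results$estimate_objects
  fmt <- vapply(names(ests), function(nm) {
    x <- ests[[nm]]
    if (!is.finite(x$estimate)) return("NE")
    if (startsWith(nm, "penetrance")) render_estimate(x, "ratio_percent")
    else if (startsWith(nm, "or_") || startsWith(nm, "hr_"))
      render_estimate(x, "value_ci")
    else render_estimate(x, "percent_ci")
  }, character(1))
  est_tab <- data.frame(estimate = names(ests), rendered = fmt,
                        row.names = NULL, stringsAsFactors = FALSE)

  cr_tab <- NULL
  if (!is.null(results$cumulative_risk)) {
    cr <- results$cumulative_risk
    cell <- function(r, lo, hi) {
      if (is.na(r)) return("-")
      if (r == 0) return("0 (0 to 0)")
      sprintf("%s (%s-%s)", formatC(signif(r, 2), format = "fg"),
              formatC(signif(lo, 2), format = "fg"),
              formatC(signif(hi, 2), format = "fg"))
    }
    cr_tab <- data.frame(
      age = cr$age,
      cumulative_risk = mapply(cell, cr$risk_percent, cr$ci_low,
                               cr$ci_high),
      stringsAsFactors = FALSE)
  }
  list(estimates = est_tab, cumulative_risk = cr_tab)
}

#' @export
print.gmmp_results <- function(x, ...) {
  cat("gmmp results bundle\n")
  cat("  cohort: ", nrow(x$cohort), " individuals (",
      sum(x$cohort$carrier_status == "HETEROZYGOTE"), " heterozygotes)\n",
      sep = "")
  cat("  estimates:\n")
  print(x$estimates[, c("name", "estimate", "ci_low", "ci_high",
                        "p_value")], digits = 3)
  invisible(x)
}
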