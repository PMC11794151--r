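# Independent oracles, kept deliberately separate from the package's
# code paths: a straight-line re-implementation of the triage flowchart,
# the textbook Wilson-with-continuity-correction interval, and
# exhaustive hypergeometric enumeration for the 2x2 exact test.

# one call at a time, plain if/else down the flowchart
oracle_classify <- function(call, cfg = triage_config()) {
  if (call$vaf < cfg$vaf_low || call$vaf > cfg$vaf_high ||
      call$gq <= cfg$gq_min_exclusive)
    return("EXCLUDED_QC")
  if (!call$consequence %in% cfg$allowed_consequences) return("NOT_USED")
  afs <- unlist(call[grep("^af_", names(call))])
  if (length(afs) && any(afs >= cfg$maf_threshold, na.rm = TRUE))
    return("NOT_USED")
  cv <- call$clinvar; iv <- call$intervar
  if (cv %in% c("P", "LP")) return("P_LP")
  if (iv %in% c("P", "LP") && !cv %in% c("B", "LB")) return("P_LP")
  votes <- 0
  if (!is.na(call$cadd) && call$cadd > cfg$cadd_min) votes <- votes + 1
  if (!is.na(call$metasvm) && call$metasvm == "D") votes <- votes + 1
  if (!is.na(call$revel) && call$revel > cfg$revel_min) votes <- votes + 1
  if (!is.na(call$bayesdel) && call$bayesdel == "D") votes <- votes + 1
  if (!is.na(call$eigen) && call$eigen > cfg$eigen_min) votes <- votes + 1
  splice <- sum(c(isTRUE(call$spidex_splice), isTRUE(call$spliceai_splice),
                  isTRUE(call$hsf_splice)))
  vus <- !cv %in% c("B", "LB") &&
    (cv %in% c("VUS", "CONFLICTING") || iv == "VUS")
  if (vus && (votes >= cfg$insilico_vote_min ||
              splice >= cfg$splice_vote_min))
    return("dVUS")
  "NOT_USED"
}

# random call generator spanning every flowchart branch
random_calls <- function(n, seed = 1) {
  set.seed(seed)
  classes <- c("P", "LP", "VUS", "LB", "B", "CONFLICTING", "ABSENT")
  data.frame(
    person_id = sprintf("R%05d", seq_len(n)),
    variant_id = sprintf("v%05d", sample.int(n, n, TRUE)),
    gene = sample(gmmp_panel(), n, TRUE),
    consequence = sample(c("missense", "nonsense", "frameshift",
                           "splice_site", "inframe_indel", "synonymous",
                           "other"), n, TRUE),
    clinvar = sample(classes, n, TRUE),
    intervar = sample(classes, n, TRUE),
    cadd = ifelse(runif(n) < 0.2, NA, round(runif(n, 0, 45), 1)),
    metasvm = ifelse(runif(n) < 0.2, NA, sample(c("D", "T"), n, TRUE)),
    revel = ifelse(runif(n) < 0.2, NA, round(runif(n), 3)),
    bayesdel = ifelse(runif(n) < 0.2, NA, sample(c("D", "T"), n, TRUE)),
    eigen = ifelse(runif(n) < 0.2, NA, round(runif(n, -2, 2), 3)),
    spidex_splice = sample(c(TRUE, FALSE, NA), n, TRUE),
    spliceai_splice = sample(c(TRUE, FALSE, NA), n, TRUE),
    hsf_splice = sample(c(TRUE, FALSE, NA), n, TRUE),
    vaf = round(runif(n, 0.05, 0.95), 3),
    gq = sample(5:99, n, TRUE),
    af_NFE = ifelse(runif(n) < 0.1, NA,
                    signif(runif(n, 0, 0.03), 3)),
    af_AFR = signif(runif(n, 0, 0.03), 3),
    stringsAsFactors = FALSE)
}

# Wilson score interval with continuity correction (textbook form)
oracle_wilson_cc <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  lo <- (2 * n * p + z^2 - 1 -
         z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
        (2 * (n + z^2))
  hi <- (2 * n * p + z^2 + 1 +
         z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
        (2 * (n + z^2))
  c(max(0, lo), min(1, hi))
}

# two-sided Fisher p by enumerating every table with the fixed margins
oracle_fisher_enum <- function(a, b, c_, d) {
  m <- a + b; n2 <- c_ + d; k <- a + c_
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# small fully-specified call table used across tests
fixture_calls <- function() {
  base <- random_calls(1, seed = 99)[0, ]
  row <- function(pid, vid, gene, cons = "missense", clinvar = "ABSENT",
                  intervar = "ABSENT", cadd = NA, metasvm = NA, revel = NA,
                  bayesdel = NA, eigen = NA, spidex = NA, spliceai = NA,
                  hsf = NA, vaf = 0.5, gq = 80, af_NFE = 1e-4,
                  af_AFR = 1e-4) {
    data.frame(person_id = pid, variant_id = vid, gene = gene,
               consequence = cons, clinvar = clinvar, intervar = intervar,
               cadd = cadd, metasvm = metasvm, revel = revel,
               bayesdel = bayesdel, eigen = eigen, spidex_splice = spidex,
               spliceai_splice = spliceai, hsf_splice = hsf, vaf = vaf,
               gq = gq, af_NFE = af_NFE, af_AFR = af_AFR,
               stringsAsFactors = FALSE)
  }
  rbind(
    base,
    row("I1", "v_runx1_lp", "RUNX1", "frameshift", clinvar = "LP"),
    row("I2", "v_runx1_lp", "RUNX1", "frameshift", clinvar = "LP"),
    row("I3", "v_runx1_lp", "RUNX1", "frameshift", clinvar = "LP"),
    row("I4", "v_ddx41_p", "DDX41", "nonsense", intervar = "P"),
    row("I5", "v_ddx41_qc", "DDX41", "nonsense", clinvar = "P",
        vaf = 0.10),
    row("I6", "v_gata2_vus", "GATA2", "missense", clinvar = "VUS",
        cadd = 25, metasvm = "D", revel = 0.8),
    row("I7", "v_etv6_splice", "ETV6", "splice_site", clinvar = "VUS",
        spidex = TRUE, spliceai = TRUE),
    row("I8", "v_cebpa_b", "CEBPA", "missense", clinvar = "B",
        intervar = "LP"),
    row("I9", "v_srp72_common", "SRP72", "missense", clinvar = "LP",
        af_NFE = 0.02),
    row("I10", "v_mecom_syn", "MECOM", "synonymous", clinvar = "LP")
  )
}
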