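## Variant triage: partitions every observed call into P_LP, dVUS,
## NOT_USED or EXCLUDED_QC following a fixed rule order. QC is evaluated
## first: a carrier of a pathogenic variant failing VAF/GQ must end up
## EXCLUDED_QC (and later be removed from the cohort entirely), never P_LP.

#' Triage configuration
#'
#' Thresholds for the variant filtering and curation rules. All numeric
#' score thresholds are strict (a CADD of exactly 20 does not vote
#' deleterious; GQ must exceed 30); the VAF window is inclusive at both
#' ends.
#'
#' @param maf_threshold Population allele-frequency cut-off: a variant is
#'   rare only if every subpopulation AF is strictly below this.
#' @param vaf_low,vaf_high Inclusive variant-allele-fraction window that
#'   screens out likely somatic / clonal-hematopoiesis calls.
#' @param gq_min_exclusive Genotype quality must strictly exceed this.
#' @param insilico_vote_min Deleteriousness votes (out of 5) needed for a
#'   VUS to be promoted to dVUS.
#' @param splice_vote_min Splice-predictor votes (out of 3) needed for a
#'   VUS to be promoted to dVUS.
#' @param cadd_min,revel_min,eigen_min Strict lower bounds for the three
#'   numeric deleteriousness scores.
#' @param allowed_consequences Consequence classes eligible for curation
#'   (exonic nonsynonymous plus splice).
#' @param panel Gene panel; calls outside it are rejected on validation.
#' @param dvus_promotions Character vector of `variant_id`s a manual
#'   literature curation has promoted from dVUS to P/LP. Empty by default:
#'   the reference curation promoted none.
#'
#' @return A list of class `triage_config`.
#' @export
triage_config <- function(maf_threshold = 0.01,
                          vaf_low = 0.35, vaf_high = 0.65,
                          gq_min_exclusive = 30,
                          insilico_vote_min = 3,
                          splice_vote_min = 2,
                          cadd_min = 20, revel_min = 0.5, eigen_min = 0,
                          allowed_consequences = c("missense", "nonsense",
                                                   "frameshift", "splice_site",
                                                   "inframe_indel"),
                          panel = gmmp_panel(),
                          dvus_promotions = character()) {
  stopifnot(is.numeric(maf_threshold), maf_threshold > 0,
            is.numeric(vaf_low), is.numeric(vaf_high),
            0 <= vaf_low, vaf_low < vaf_high, vaf_high <= 1,
            is.numeric(gq_min_exclusive))
  structure(list(maf_threshold = maf_threshold, vaf_low = vaf_low,
                 vaf_high = vaf_high, gq_min_exclusive = gq_min_exclusive,
                 insilico_vote_min = insilico_vote_min,
                 splice_vote_min = splice_vote_min,
                 cadd_min = cadd_min, revel_min = revel_min,
                 eigen_min = eigen_min,
                 allowed_consequences = allowed_consequences,
                 panel = panel, dvus_promotions = dvus_promotions),
            class = "triage_config")
}

af_columns <- function(calls) grep("^af_", names(calls), value = TRUE)

#' Population-frequency filter
#'
#' A variant passes if its allele frequency is below the threshold in
#' every reference subpopulation. A variant absent from the reference
#' database (no AF at all) passes: absence implies rarity, and panels of
#' this kind contain private variants.
#'
#' @param subpop_af Named numeric vector of subpopulation allele
#'   frequencies for one call, or a data frame / matrix (calls x
#'   subpopulations, `NA` = absent); all values must lie in \[0, 1\].
#' @param cfg A [triage_config()].
#' @return Logical (one per call).
#' @export
#' @examples
#' passes_frequency_filter(c(NFE = 5e-4, AFR = 1e-4))  # TRUE
#' passes_frequency_filter(c(NFE = 5e-4, EAS = 0.02))  # FALSE
#' passes_frequency_filter(numeric(0))                 # TRUE (absent = rare)
passes_frequency_filter <- function(subpop_af, cfg = triage_config()) {
  af <- if (is.data.frame(subpop_af)) as.matrix(subpop_af) else subpop_af
  if (any(af < 0 | af > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  if (is.matrix(af)) {
    if (ncol(af) == 0L) return(rep(TRUE, nrow(af)))
    apply(af, 1L, function(r) all(r < cfg$maf_threshold, na.rm = TRUE))
  } else {
    all(af < cfg$maf_threshold, na.rm = TRUE)
  }
}

#' Genotype-level quality control
#'
#' `PASS` requires a VAF inside the inclusive heterozygote window and a
#' genotype quality strictly above the cut-off. VAF is checked first, so a
#' call failing both reports `FAIL_VAF`.
#'
#' @param vaf,gq Numeric vectors (mandatory; missing values are an error).
#' @param cfg A [triage_config()].
#' @return Character vector: `"PASS"`, `"FAIL_VAF"` or `"FAIL_GQ"`.
#' @export
#' @examples
#' genotype_qc(0.50, 99)  # PASS
#' genotype_qc(0.35, 30)  # FAIL_GQ: 0.35 is inside the window, GQ 30 is not
genotype_qc <- function(vaf, gq, cfg = triage_config()) {
  if (anyNA(vaf) || anyNA(gq))
    stop("vaf and gq are mandatory QC fields and must not be missing")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  if (any(gq < 0)) stop("gq must be non-negative")
  out <- rep("PASS", length(vaf))
  out[gq <= cfg$gq_min_exclusive] <- "FAIL_GQ"
  out[vaf < cfg$vaf_low | vaf > cfg$vaf_high] <- "FAIL_VAF"
  out
}

vote_enum_d <- function(x) !is.na(x) & x == "D"

#' In-silico deleteriousness vote
#'
#' Counts, per call, how many of the five prediction tools vote
#' deleterious: CADD above 20, MetaSVM "D", REVEL above 0.5, BayesDel "D",
#' Eigen above 0 (all strict). A missing score never votes.
#'
#' @param cadd,revel,eigen Numeric score vectors (`NA` = missing).
#' @param metasvm,bayesdel Character vectors with `"D"`/`"T"` (`NA` =
#'   missing).
#' @param cfg A [triage_config()].
#' @return Integer vector in 0..5.
#' @export
#' @examples
#' deleteriousness_vote(25, "D", 0.7, "D", 0.5)   # 5
#' deleteriousness_vote(20, "T", 0.5, "T", 0)     # 0 (boundaries don't vote)
#' deleteriousness_vote(21, "D", 0.3, NA, NA)     # 2
deleteriousness_vote <- function(cadd = NA_real_, metasvm = NA_character_,
                                 revel = NA_real_, bayesdel = NA_character_,
                                 eigen = NA_real_, cfg = triage_config()) {
  n <- max(length(cadd), length(metasvm), length(revel), length(bayesdel),
           length(eigen))
  v <- (!is.na(cadd) & cadd > cfg$cadd_min) +
       vote_enum_d(rep_len(metasvm, n)) +
       (!is.na(revel) & revel > cfg$revel_min) +
       vote_enum_d(rep_len(bayesdel, n)) +
       (!is.na(eigen) & eigen > cfg$eigen_min)
  as.integer(v)
}

#' Splice-prediction vote
#'
#' Counts, per call, how many of the three splice predictors (Spidex,
#' SpliceAI, Human Splicing Finder) flag the variant as splice-affecting.
#' Predictions arrive as pre-computed booleans; missing = no vote.
#'
#' @param spidex,spliceai,hsf Logical vectors (`NA` = missing).
#' @return Integer vector in 0..3.
#' @export
#' @examples
#' splice_vote(TRUE, TRUE, FALSE) # 2
#' splice_vote(FALSE, NA, NA)     # 0
splice_vote <- function(spidex = NA, spliceai = NA, hsf = NA) {
  as.integer((!is.na(spidex) & spidex) + (!is.na(spliceai) & spliceai) +
             (!is.na(hsf) & hsf))
}

plp_classes <- c("P", "LP")
benign_classes <- c("B", "LB")

validate_calls <- function(calls, cfg) {
  required <- c("person_id", "variant_id", "gene", "consequence",
                "clinvar", "intervar", "vaf", "gq")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols))
    stop("variant call table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_gene <- setdiff(unique(calls$gene), cfg$panel)
  if (length(bad_gene))
    stop("gene(s) outside the configured panel: ",
         paste(bad_gene, collapse = ", "))
  score_cols <- c("cadd", "metasvm", "revel", "bayesdel", "eigen",
                  "spidex_splice", "spliceai_splice", "hsf_splice")
  for (col in setdiff(score_cols, names(calls))) calls[[col]] <- NA
  cls <- c("P", "LP", "VUS", "LB", "B", "CONFLICTING", "ABSENT")
  for (col in c("clinvar", "intervar")) {
    calls[[col]] <- toupper(as.character(calls[[col]]))
    calls[[col]][is.na(calls[[col]]) | calls[[col]] == ""] <- "ABSENT"
    bad <- setdiff(unique(calls[[col]]), cls)
    if (length(bad))
      stop("unknown ", col, " class: ", paste(bad, collapse = ", "))
  }
  calls
}

#' Triage a table of annotated variant calls
#'
#' Applies the filtering and curation flowchart to every
#' (individual, variant) call, in a fixed rule order:
#' \enumerate{
#'   \item genotype QC failure (VAF outside the heterozygote window, or
#'     low GQ) -> `EXCLUDED_QC`;
#'   \item disallowed consequence class, or population frequency at or
#'     above the MAF threshold in any subpopulation -> `NOT_USED`;
#'   \item ClinVar or InterVar asserts P/LP -> `P_LP`; a curated ClinVar
#'     benign/likely-benign assertion overrides an automated InterVar
#'     P/LP; ClinVar "CONFLICTING" is treated as VUS;
#'   \item a VUS designation (either source) backed by at least 3 of 5
#'     deleteriousness votes or at least 2 of 3 splice votes -> `dVUS`
#'     (a configured manual-promotion list may then lift it to `P_LP`);
#'   \item everything else (unsupported VUS, benign, absent from both
#'     sources) -> `NOT_USED`.
#' }
#' Homozygous calls (optional `zygosity` column, value `"hom"`) are
#' excluded with a warning.
#'
#' @param calls Data frame with one row per (person, variant) call;
#'   columns `person_id`, `variant_id`, `gene`, `consequence`, `clinvar`,
#'   `intervar`, `vaf`, `gq`, optional score columns (`cadd`, `metasvm`,
#'   `revel`, `bayesdel`, `eigen`), splice flags (`spidex_splice`,
#'   `spliceai_splice`, `hsf_splice`), subpopulation allele frequencies as
#'   `af_<POP>` columns, and optional `zygosity`.
#' @param cfg A [triage_config()].
#' @return The input with columns `classification` (one of `P_LP`,
#'   `dVUS`, `NOT_USED`, `EXCLUDED_QC`), `deleterious_votes`,
#'   `splice_votes`, `qc_status` and `rule_trail` (the ordered gate
#'   evaluations, serialized `rule=pass|fail` and `;`-separated) appended.
#' @export
triage_variants <- function(calls, cfg = triage_config()) {
  calls <- validate_calls(calls, cfg)
  n <- nrow(calls)
  afc <- af_columns(calls)
  freq_ok <- passes_frequency_filter(calls[afc], cfg)
  qc <- genotype_qc(calls$vaf, calls$gq, cfg)
  dvotes <- deleteriousness_vote(calls$cadd, calls$metasvm, calls$revel,
                                 calls$bayesdel, calls$eigen, cfg)
  svotes <- splice_vote(calls$spidex_splice, calls$spliceai_splice,
                        calls$hsf_splice)
  hom <- if ("zygosity" %in% names(calls))
    !is.na(calls$zygosity) & tolower(calls$zygosity) == "hom"
  else rep(FALSE, n)
  if (any(hom))
    warning(sum(hom), " homozygous call(s) excluded from triage")

  cons_ok <- calls$consequence %in% cfg$allowed_consequences
  cv <- calls$clinvar; iv <- calls$intervar
  is_plp <- (cv %in% plp_classes) |
    (iv %in% plp_classes & !(cv %in% benign_classes))
  vus_designated <- (!(cv %in% benign_classes)) &
    (cv %in% c("VUS", "CONFLICTING") | iv == "VUS")
  dvus_evidence <- dvotes >= cfg$insilico_vote_min |
    svotes >= cfg$splice_vote_min

  classification <- rep("NOT_USED", n)
  classification[vus_designated & dvus_evidence] <- "dVUS"
  classification[classification == "dVUS" &
                 calls$variant_id %in% cfg$dvus_promotions] <- "P_LP"
  classification[is_plp] <- "P_LP"
  classification[!cons_ok | !freq_ok] <- "NOT_USED"
  classification[qc != "PASS"] <- "EXCLUDED_QC"
  classification[hom] <- "NOT_USED"

  pf <- function(x) ifelse(x, "pass", "fail")
  trail <- if (n == 0L) character(0) else
    paste0("vaf=", pf(qc != "FAIL_VAF"),
                  ";gq=", pf(qc == "PASS"),
                  ";consequence=", pf(cons_ok),
                  ";maf=", pf(freq_ok),
                  ";pathogenic=", pf(is_plp),
                  ";vus_deleterious=", pf(vus_designated & dvus_evidence))
  trail[hom] <- paste0("zygosity=fail;", trail[hom])

  calls$classification <- classification
  calls$deleterious_votes <- dvotes
  calls$splice_votes <- svotes
  calls$qc_status <- qc
  calls$rule_trail <- trail
  calls
}

#' Per-gene variant and heterozygote burden
#'
#' Tallies unique P/LP and dVUS variants and the individuals carrying
#' them, per gene and over the whole panel. An individual with P/LP calls
#' in two genes counts once in the all-gene total and once per gene.
#'
#' @param triage Output of [triage_variants()].
#' @param panel Gene panel (rows are emitted for every panel gene, zero
#'   counts included).
#' @return Data frame with one row per gene plus an `ALL` row: columns
#'   `gene`, `n_P_LP_variants`, `n_heterozygotes`, `n_dVUS_variants`,
#'   `n_dVUS_individuals`.
#' @export
summarize_gene_burden <- function(triage, panel = gmmp_panel()) {
  bad <- setdiff(unique(triage$gene), panel)
  if (length(bad))
    stop("gene(s) outside the panel: ", paste(bad, collapse = ", "))
  tally <- function(rows) {
    c(n_P_LP_variants = length(unique(rows$variant_id[
        rows$classification == "P_LP"])),
      n_heterozygotes = length(unique(rows$person_id[
        rows$classification == "P_LP"])),
      n_dVUS_variants = length(unique(rows$variant_id[
        rows$classification == "dVUS"])),
      n_dVUS_individuals = length(unique(rows$person_id[
        rows$classification == "dVUS"])))
  }
  per_gene <- t(vapply(panel, function(g) tally(triage[triage$gene == g, ]),
                       numeric(4)))
  out <- data.frame(gene = c(panel, "ALL"),
                    rbind(per_gene, tally(triage)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
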