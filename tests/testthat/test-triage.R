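# Variant triage: gate logic, rule ordering, flowchart properties.

test_that("frequency filter requires rarity in every subpopulation", {
  expect_true(passes_frequency_filter(c(NFE = 5e-4, AFR = 1e-4)))
  expect_false(passes_frequency_filter(c(NFE = 5e-4, EAS = 0.02)))
  expect_true(passes_frequency_filter(numeric(0)))  # absent = rare
  expect_true(passes_frequency_filter(c(NFE = NA, AFR = 1e-4)))
  expect_false(passes_frequency_filter(c(NFE = 0.01)))  # at threshold
  expect_error(passes_frequency_filter(c(NFE = 1.2)), "\\[0, 1\\]")
  # matrix form, one row per call
  m <- rbind(c(1e-4, 1e-4), c(1e-4, 0.05))
  expect_identical(passes_frequency_filter(m), c(TRUE, FALSE))
})

test_that("genotype QC window is inclusive on VAF, strict on GQ", {
  expect_identical(genotype_qc(0.50, 99), "PASS")
  expect_identical(genotype_qc(0.30, 99), "FAIL_VAF")
  expect_identical(genotype_qc(0.35, 30), "FAIL_GQ")
  expect_identical(genotype_qc(c(0.35, 0.65, 0.651), c(31, 31, 31)),
                   c("PASS", "PASS", "FAIL_VAF"))
  # VAF reported first when both gates fail
  expect_identical(genotype_qc(0.1, 10), "FAIL_VAF")
  expect_error(genotype_qc(NA, 50), "mandatory")
  expect_error(genotype_qc(0.5, NA), "mandatory")
})

test_that("deleteriousness votes use strict thresholds, missing = no vote", {
  expect_identical(deleteriousness_vote(25, "D", 0.7, "D", 0.5), 5L)
  expect_identical(deleteriousness_vote(20, "T", 0.5, "T", 0), 0L)
  expect_identical(deleteriousness_vote(21, "D", 0.3, NA, NA), 2L)
  expect_identical(deleteriousness_vote(NA, NA, NA, NA, NA), 0L)
})

test_that("splice votes count true flags, missing = false", {
  expect_identical(splice_vote(TRUE, TRUE, FALSE), 2L)
  expect_identical(splice_vote(FALSE, NA, NA), 0L)
  expect_identical(splice_vote(TRUE, TRUE, TRUE), 3L)
})

test_that("classification follows the fixed rule order", {
  tri <- triage_variants(fixture_calls())
  cls <- setNames(tri$classification, tri$person_id)
  expect_identical(unname(cls[c("I1", "I4")]), c("P_LP", "P_LP"))
  # QC precedes pathogenicity: a pathogenic call with somatic-range VAF
  # is excluded entirely, not counted as a carrier
  expect_identical(unname(cls["I5"]), "EXCLUDED_QC")
  expect_identical(unname(cls["I6"]), "dVUS")   # VUS + 3 in-silico votes
  expect_identical(unname(cls["I7"]), "dVUS")   # VUS + 2 splice votes
  # curated ClinVar benign overrides automated InterVar P/LP
  expect_identical(unname(cls["I8"]), "NOT_USED")
  expect_identical(unname(cls["I9"]), "NOT_USED")   # common allele
  expect_identical(unname(cls["I10"]), "NOT_USED")  # synonymous
  # rule trail records every gate for audit
  expect_match(tri$rule_trail[tri$person_id == "I5"], "vaf=fail")
  expect_match(tri$rule_trail[tri$person_id == "I1"], "pathogenic=pass")
})

test_that("every call lands in exactly one class and the split is exhaustive", {
  calls <- random_calls(2000, seed = 11)
  tri <- triage_variants(calls)
  expect_identical(nrow(tri), nrow(calls))
  tab <- table(factor(tri$classification,
                      c("P_LP", "dVUS", "NOT_USED", "EXCLUDED_QC")))
  expect_identical(sum(tab), nrow(calls))
  # EXCLUDED_QC exactly when the genotype filter failed
  expect_identical(tri$classification == "EXCLUDED_QC",
                   tri$qc_status != "PASS")
  # vote bound: never more votes than non-missing scores
  n_scores <- rowSums(!is.na(calls[c("cadd", "metasvm", "revel",
                                     "bayesdel", "eigen")]))
  expect_true(all(tri$deleterious_votes <= n_scores))
})

test_that("classification matches the straight-line flowchart oracle", {
  calls <- random_calls(10000, seed = 42)
  tri <- triage_variants(calls)
  expected <- vapply(seq_len(nrow(calls)),
                     function(i) oracle_classify(calls[i, ]),
                     character(1))
  expect_identical(tri$classification, expected)
})

test_that("triage is deterministic and votes are monotone in each score", {
  calls <- random_calls(300, seed = 7)
  t1 <- triage_variants(calls)
  t2 <- triage_variants(calls)
  expect_identical(t1, t2)

  # raising any single deleteriousness score never demotes dVUS -> NOT_USED
  vus <- calls
  vus$clinvar <- "VUS"; vus$vaf <- 0.5; vus$gq <- 80
  vus$consequence <- "missense"
  vus$af_NFE <- 1e-4; vus$af_AFR <- 1e-4
  base <- triage_variants(vus)$classification
  for (col in c("cadd", "revel", "eigen")) {
    up <- vus
    up[[col]] <- pmax(up[[col]], 100, na.rm = FALSE)
    up[[col]][is.na(up[[col]])] <- 100
    upc <- triage_variants(up)$classification
    expect_false(any(base == "dVUS" & upc == "NOT_USED"), info = col)
  }
  for (col in c("metasvm", "bayesdel")) {
    up <- vus
    up[[col]] <- "D"
    upc <- triage_variants(up)$classification
    expect_false(any(base == "dVUS" & upc == "NOT_USED"), info = col)
  }
})

test_that("homozygous calls are excluded with a warning", {
  calls <- fixture_calls()
  calls$zygosity <- c("hom", rep("het", nrow(calls) - 1))
  expect_warning(tri <- triage_variants(calls), "homozygous")
  expect_identical(tri$classification[1], "NOT_USED")
  expect_match(tri$rule_trail[1], "zygosity=fail")
})

test_that("a configured promotion list lifts named dVUS to P/LP", {
  cfg <- triage_config(dvus_promotions = "v_gata2_vus")
  tri <- triage_variants(fixture_calls(), cfg)
  expect_identical(tri$classification[tri$person_id == "I6"], "P_LP")
  # by default no dVUS is promoted
  tri0 <- triage_variants(fixture_calls())
  expect_identical(tri0$classification[tri0$person_id == "I6"], "dVUS")
})

test_that("gene burden tallies unique variants and individuals", {
  tri <- triage_variants(fixture_calls())
  burden <- summarize_gene_burden(tri)
  g <- function(gene, col) burden[burden$gene == gene, col]
  # one variant shared by three people
  expect_identical(g("RUNX1", "n_P_LP_variants"), 1)
  expect_identical(g("RUNX1", "n_heterozygotes"), 3)
  # QC-excluded DDX41 call does not count
  expect_identical(g("DDX41", "n_P_LP_variants"), 1)
  expect_identical(g("DDX41", "n_heterozygotes"), 1)
  expect_identical(g("GATA2", "n_dVUS_variants"), 1)
  expect_identical(g("ALL", "n_P_LP_variants"), 2)
  expect_identical(g("ALL", "n_heterozygotes"), 4)
  # empty input gives all zeros
  empty <- summarize_gene_burden(tri[0, ])
  expect_true(all(empty[, -1] == 0))
  expect_error(summarize_gene_burden(data.frame(
    gene = "TP53", person_id = "x", variant_id = "v",
    classification = "P_LP")), "panel")
})

test_that("a person with two P/LP calls counts once in the panel total", {
  calls <- rbind(fixture_calls(),
                 within(fixture_calls()[1, ], {
                   person_id <- "I1"; variant_id <- "v_ddx41_p"
                   gene <- "DDX41"
                 }))
  burden <- summarize_gene_burden(triage_variants(calls))
  expect_identical(burden[burden$gene == "ALL", "n_heterozygotes"], 4)
  expect_identical(burden[burden$gene == "DDX41", "n_heterozygotes"], 2)
})
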