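---
title: "Methods: genome-first triage and risk estimation for germline myeloid predisposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-first triage and risk estimation for germline myeloid predisposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmmp)
```

## The problem

About one in ten myeloid malignancies arises on a germline predisposition.
Eight autosomal-dominant genes — *ANKRD26*, *CEBPA*, *DDX41*, *ETV6*,
*GATA2*, *MECOM*, *RUNX1*, *SRP72* — are recurrently implicated, but
penetrance estimates from clinically ascertained families are biased
upward: families come to attention *because* someone got sick. The
genome-first alternative ascertains carriers on genotype alone in
population biobanks linked to electronic health records (EHR), then asks
how often those carriers actually develop disease and whether they die
earlier. `gmmp` implements that analysis end to end: rule-based variant
triage, ICD-coded phenotype harmonization, cohort assembly, and the
epidemiological estimates such a study reports — plus a synthetic-cohort
generator with known ground truth, so every step is testable without
access to restricted biobank data.

## Variant triage

Each (individual, variant) call is pushed through a fixed rule order;
the first decisive gate wins, and every gate evaluation is recorded in a
rule trail for audit.

1. **Genotype QC.** Heterozygous germline calls should sit near 50%
   variant allele fraction; VAF outside the inclusive window
   [0.35, 0.65] is the signature of somatic / clonal-hematopoiesis
   contamination from the blood-derived DNA, and genotype quality must
   strictly exceed 30. A failing call is `EXCLUDED_QC`, *before*
   pathogenicity is even considered — and the person carrying it is
   later removed from the analyses entirely, because their carrier
   status is unknowable rather than negative.
2. **Scope and rarity.** Only exonic nonsynonymous and splice
   consequences are curated, and the allele frequency must be < 0.01 in
   *every* reference subpopulation. A variant absent from the frequency
   reference passes: absence implies rarity, and panels like this one
   are full of private variants.
3. **Pathogenic assertion.** ClinVar or InterVar P/LP makes the call
   `P_LP`. When the two disagree, a curated ClinVar benign/likely-benign
   assertion overrides the automated InterVar classifier (a human
   curation outranks a rule engine); ClinVar "conflicting
   interpretations" is treated as VUS.
4. **Deleterious VUS.** A VUS (from either source) is promoted to
   `dVUS` when at least 3 of 5 in-silico tools vote deleterious —
   CADD > 20, MetaSVM = D, REVEL > 0.5, BayesDel = D, Eigen > 0, all
   strict, with a missing score never voting — or at least 2 of 3
   splice predictors (Spidex, SpliceAI, Human Splicing Finder) flag the
   variant. Splice predictions arrive as pre-computed booleans because
   the underlying numeric cutoffs are tool- and release-specific; a
   user applying SpliceAI directly would typically call delta ≥ 0.2
   splice-affecting, but that is an implementation default of the
   annotation step, not part of this package's rules.
5. **Everything else** — unsupported VUS, benign, absent from both
   sources, out-of-scope consequences, common alleles — is `NOT_USED`.

dVUS variants count toward carrier-frequency summaries only; phenotype
analyses use P/LP carriers exclusively. Manual literature curation of
dVUS is modelled as an identity pass (a configurable promotion list
exists, empty by default), reflecting the observation that systematic
database review typically promotes none of them. Missing in-silico
scores deliberately do not vote: the conservative direction is to leave
an unannotated variant unpromoted. Homozygous calls are excluded with a
warning — none are expected for these dominant, largely truncating
alleles.

## Phenotype harmonization and cohort assembly

Diagnosis streams mix ICD-9, ICD-10 and ICD-10-CM codes. Codes map to
canonical malignancy groups by longest normalized prefix; the shipped
map covers hematological malignancies (HM: ICD-10 C81–C96, D45–D47,
ICD-9 200–208, 238.7x) with a myeloid subset (MM: C92–C94, D45, D46,
D47.1, D47.3; ICD-9 205–206, 238.72–238.75). Institutional code lists
vary, so the map is a YAML-overridable default rather than an
authority.

Repeated codes are reconciled into episodes: within a malignancy group,
a record joins the open episode if it falls within five years of the
episode's *most recent* record or is coded as a relapse; otherwise it
opens a second, separate malignancy. Chaining to the most recent record
(rather than the episode anchor) merges continuous care for one disease
even when it spans more than five years — the alternative would
manufacture second malignancies out of long treatment histories. Episode
multiplicity never changes penetrance, which is per-person ever/never.

One row per person then carries carrier status (any passing P/LP call →
heterozygote; only QC-failed panel evidence → excluded; otherwise
control), covariates (sex, age, BMI, ever-smoking, race), outcome flags
with first-onset ages, and survival fields. Missing covariates survive
assembly and are removed per model fit (complete-case within each
model), so one missing BMI does not cost a person their prevalence
contribution.

## Estimation

**Proportions.** Prevalence (carriers / cohort) and penetrance
(affected carriers / carriers) get Wilson score intervals with
continuity correction — the default behaviour of R's `prop.test`, which
is what studies of this design cite. Printed-precision conventions are
fixed and deliberately reproduced: percentages round half-up to one
decimal, carrier frequencies render as `1:N` with
N = round-half-up(denominator/numerator). These conventions are what
make the package's output comparable digit-for-digit with published
tables (e.g. `penetrance(5, 196)` renders `1:39 [2.6%]`).

**Group comparisons.** Categorical risk factors use Fisher's exact test
(two-sided, by hypergeometric tail summation); continuous ones use the
Welch two-sample t-test. The choice of Welch is ours: comparison tables
in this literature typically name only the categorical test, and Welch
is the safe default when group variances differ by orders of magnitude
of sample size.

**Odds ratios.** The carrier effect on HM/MM is a maximum-likelihood
logistic regression adjusted for age, sex, BMI and smoking (the set is
configurable — a gene stratum with, say, no smokers gets the degenerate
covariate dropped with a warning rather than a singular fit). With no
covariates the fitted OR equals the crude cross-product OR, which the
package also computes with a Woolf interval and Haldane–Anscombe
correction as a sanity companion. Complete separation is detected and
reported as non-estimable instead of returning a meaningless 10^8.

**Survival.** The default clock is age with left truncation at entry:
a person first seen at 60 contributes to risk sets only from 60, which
is what the mixed retrospective/prospective EHR designs require;
ignoring delayed entry would credit carriers with immortal person-time.
Kaplan-Meier estimates use `survival::survfit` with Greenwood variance
and log-log intervals. The log-rank comparison uses `survival::survdiff`
when entry is common, and the Cox score test — the log-rank
generalization for counting-process data — under delayed entry, where
`survdiff` does not apply. Hazard ratios come from `survival::coxph`
with Breslow tie handling (ties are rare on a continuous age scale; the
choice is the conventional default). A three-month landmark excludes
malignancy diagnoses within 0.25 years of first encounter from
time-to-event analyses only, so prevalent disease discovered at intake
does not masquerade as incident risk; prevalence and penetrance counts
are never landmarked. Administrative censoring is applied on ingest.

**Cumulative risk** tabulates `1 − S(age)` at ages 0, 10, …, 90 as
percentages. Decades beyond observed follow-up print as `-`; ages with
an event-free risk set print `0 (0 to 0)` — both conventions taken from
the tables this output is meant to sit beside. Estimates are stored raw
and unrounded; rendering is a separate pass, so no precision is lost to
formatting.

No multiple-testing adjustment is applied anywhere; p-values are
reported unadjusted, matching field practice for these descriptive
cohort papers, and users combining many genes and outcomes should
correct downstream.

## The synthetic cohort

The generator's defaults are the study conditions the package is
validated under, chosen once from the population figures this kind of
cohort reports: carrier prevalence 1/500 (observed range roughly
1:450–1:600); a gene mix dominated by *DDX41* (~70% of carriers) with
the transcription factors rare; per-gene carrier HM penetrance spanning
0.017–0.33 (*DDX41* low at 0.04, *RUNX1*/*GATA2*/*ETV6* high, matching
the reported 1:39 to 1:2 spread); background HM frequency 0.025
(≈ 4215/170147); a quarter of HMs myeloid; carrier all-cause-mortality
hazard ratio 1.8; sex P(male) = 0.46, ever-smoking 0.6, BMI
Normal(29, 6), entry age truncated-Normal(50, 15) on [18, 80] with 15
years of administrative follow-up.

Mortality is piecewise-exponential in age (rates per decade rising from
5×10⁻⁴ to 0.15/year), so the true cumulative risk has the closed form
`1 − exp(−HR·Λ(t))` and Kaplan-Meier output can be checked against an
analytic oracle. Death is sampled *conditional on survival to entry*,
i.e. the emitted population is correctly left-truncated; an alternative
`left_truncate = "cohort"` mode samples from birth and drops pre-entry
deaths, which deliberately reproduces the enrollment survivorship bias
that depresses penetrance estimates for early-lethal genotypes — useful
for demonstrating that bias, not for calibration. Two outcome modes
exist: the default assigns HM from per-gene penetrances (a planted risk
difference), while `outcome_model = "logistic"` plants an exact carrier
log odds ratio with mild covariate effects, which is what the
parameter-recovery experiments use. HM onset is drawn within the
person's observed lifetime, so ground-truth outcome flags coincide with
what an EHR could record.

Each affected person emits one to three ICD codes scattered within the
five-year reconciliation window (mixing ICD-9 and ICD-10 spellings of
the same disease), occasional relapse-flagged records, and a 3% chance
of a genuine re-diagnosis more than five years later. Variant calls
cover every triage branch: P/LP-consistent calls for carriers (a
`qc_noise` fraction of which violate the VAF/GQ gates), deleterious-VUS
calls at 1.7% of individuals, and benign/common/unsupported calls.
Both tables derive from deterministic per-table substreams of one seed,
so identical seed and configuration give byte-identical fixtures.

What the generator does *not* emulate: linkage and haplotype structure,
clonal-hematopoiesis VAF drift (beyond the QC-noise knob), miscoded or
missing diagnoses, competing risks, or covariate-dependent enrollment.
Passing recovery tests therefore demonstrate that the estimators are
correct under the stated sampling model — not that any particular real
cohort satisfies that model.

## Validation experiments and problem sizes

The test suite's heavier experiments use sizes chosen to give the
relevant checks statistical teeth at desk scale:

* triage oracle equivalence on 10⁴ randomly generated calls against an
  independent straight-line re-implementation of the flowchart;
* Fisher's exact test against full hypergeometric enumeration on 300
  random tables with margins ≤ 30;
* OR/HR parameter recovery at n = 50,000 with carrier prevalence 0.01
  (≈ 500 carriers per replicate, the same carrier yield as a
  200,000-person cohort at the default prevalence), 100 seeds, planted
  OR 4.6 and HR 1.8, requiring ≥ 90% CI coverage and mean log-HR bias
  under 5%;
* null calibration: log-rank size on 200 replicates of two 500-person
  arms with identical hazards, and OR/HR coverage of 1.0 over 100
  seeds at n = 10,000 with no planted effect;
* cumulative risk against the closed-form piecewise-exponential answer
  at n = 20,000.

## Known limitations

The ICD code map is a best-effort default, not an institutional
authority; real deployments should supply their own. VAF windows cannot
fully separate germline from somatic variation, so carrier counts in
blood-derived cohorts may overestimate true germline prevalence — the
package reproduces the design, including this limitation. Copy-number
and non-coding regulatory variants (notably the *GATA2* intronic
enhancer and the *ANKRD26* 5'UTR) are out of scope at the input level:
if the upstream caller did not emit them, the panel undercounts those
genes. Competing-risks structure and between-gene frailty are not
modelled; cumulative risks are all-cause Kaplan-Meier complements.
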