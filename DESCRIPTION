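Package: gmmp
Title: Genome-First Prevalence and Penetrance of Germline Myeloid
    Malignancy Predisposition Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based triage of annotated germline variant calls in an
    eight-gene myeloid malignancy predisposition panel into
    pathogenic/likely-pathogenic, deleterious-VUS, unused and QC-excluded
    classes; harmonization of ICD-9/10 coded diagnosis streams into
    reconciled malignancy events; assembly of heterozygote/control
    analysis cohorts from individual-level phenotype records; and
    estimation of carrier prevalence, penetrance, adjusted odds ratios,
    Kaplan-Meier/Cox survival with left truncation and landmark
    filtering, and decade-binned cumulative risk. A synthetic-cohort
    generator with known ground truth allows the whole pipeline to be run
    and validated without access to restricted biobank data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
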