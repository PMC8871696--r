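Package: minorsplice
Title: Differential Minor-Intron Splicing in Matched Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies retention of minor (U12-type) introns from intron and
    junction read counts as percent-spliced-in (PSI), tests differential
    splicing between matched tumor and adjacent normal tissue with paired
    Wilcoxon signed-rank tests and Benjamini-Hochberg FDR control, summarises
    each cohort with a minor-splicing score and a binomial skew test,
    estimates per-tumor minor-splicing activity as summed standardized PSI
    deviations from the normal-tissue distribution, tests minor
    intron-containing gene (MIG) expression changes and their enrichment
    against the protein-coding background, and correlates splicing activity
    with spliceosome-component expression within and across cohorts. Ships a
    seeded synthetic-cohort generator with ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    DESeq2,
    optparse,
    knitr
Config/testthat/edition: 3
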