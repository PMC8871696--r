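# minorsplice

Differential splicing of **minor (U12-type) introns** between matched tumor
and adjacent normal tissue. About 0.5% of human introns are excised by the
minor spliceosome; their retention changes transcript fate, and the ~600
minor intron-containing genes (MIGs) are enriched in DNA-processing
functions. `minorsplice` provides a tested, reusable pipeline for asking, in
a matched tumor–normal cohort design: are minor introns spliced more or less
efficiently in tumors, are MIGs differentially expressed, and does
minor-splicing activity track the expression of minor-spliceosome
components?

## The model

For each minor intron and sample with at least one supporting read, retention
is quantified as percent spliced in:

```
PSI = 100 * COV_INT / (COV_INT + COV_EJ)
```

where `COV_INT` is the mean per-base intron coverage (total alignments to
the intron / intron length) and `COV_EJ` the number of spliced alignments
spanning the intron. High PSI = high retention = low splicing. Per matched
pair, `dPSI = PSI_normal − PSI_tumor`, so positive dPSI means more efficient
splicing in the tumor.

Per cohort, each intron with ≥ 3 complete pairs is tested with a **paired
Wilcoxon signed-rank test** (exact by sign-flip enumeration for n ≤ 25,
normal approximation with tie and continuity corrections otherwise),
adjusted by **Benjamini–Hochberg** within the cohort. The cohort's
**minor-splicing score** is

```
score = INT_up − INT_down
```

(significantly more-spliced minus significantly less-spliced introns at
FDR < 0.05), and a two-sided exact binomial test on `(INT_up, INT_down)`
classifies the cohort's skew, FDR-corrected across cohorts.

Per-tumor **minor-splicing activity** is the summed standardized deviation
from the normal-tissue PSI distribution,

```
beta_i = (mu_i − T_i) / sigma_i ,   activity = sum_i beta_i
```

with `mu_i`, `sigma_i` the mean and SD of intron *i*'s PSI across all normal
samples in the cohort and `T_i` the tumor's PSI. Per-patient activity change
is the summed dPSI. The expression layer normalizes raw gene counts with
median-of-ratios size factors, tests paired differential expression per gene
set (protein-coding, MIG, spliceosome components, stem signature), tests MIG
up-regulation enrichment against the protein-coding background with a
one-sided exact binomial test, and correlates activity with component
expression (Spearman, exact permutation p for n ≤ 7) within cohorts and
splicing scores with expression changes across cohorts.

A seeded synthetic-cohort generator (`simulation_config()` /
`simulate_study()`) emits every input format with known ground truth, so all
of the above is testable without any external download.

## Worked example

Simulate two cohorts of 15 matched pairs with 40 minor introns (10 shifted
−15 PSI points in tumors, 3 shifted +15) and 600 genes (30 MIGs up-regulated
at log2FC = 1), then run the full pipeline:

```r
library(minorsplice)
library(dplyr)

cfg <- simulation_config(
  seed = 20, cohorts = c("CH01", "CH02"), n_patients = 15, n_introns = 40,
  n_genes = 600, mig_fraction = 0.2, n_components = 8, n_stem = 10,
  psi_beta_shape = c(10, 10),
  psi_effects = bind_rows(tibble::tibble(intron = 1:10, psi_shift = -15),
                          tibble::tibble(intron = 11:13, psi_shift = 15)),
  de_effects = tibble::tibble(gene = 1:30, log2fc = 1)
)
sim <- simulate_study(cfg)
dir <- tempfile(); write_simulation(sim, dir)
res <- run_pipeline(run_config(
  annotation = file.path(dir, "annotation.bed"),
  coverage   = file.path(dir, "coverage.tsv"),
  samples    = file.path(dir, "samples.tsv"),
  gene_counts = file.path(dir, "gene_counts.tsv"),
  gene_sets   = file.path(dir, "gene_sets.tsv"),
  out_dir = file.path(dir, "out")
))
res$summary
#> # A tibble: 2 × 9
#>   cohort introns_up introns_down introns_ns score skew_class mig_up mig_down mig_ns
#> 1 CH01           12            3         25     9 none           30        2     88
#> 2 CH02           10            3         27     7 none           29        1     90
res$mig_enrichment
#> # A tibble: 2 × 6
#>   cohort n_mig_tested n_mig_up background_prop        p        q
#> 1 CH01            120       30          0.0517 4.23e-13 4.23e-13
#> 2 CH02            120       29          0.0433 3.38e-14 6.76e-14
```

Both cohorts recover a positive minor-splicing score near the injected
up/down imbalance (10 − 3; the score includes a couple of noise calls at 15
pairs), and the injected MIG up-regulation is overwhelmingly enriched over
the ~5% background of significantly up protein-coding genes. All tables
(PSI, paired dPSI, per-intron tests, activity, correlations, run manifest)
are written under `out/`.

A command-line wrapper with `simulate`, `run` and `report` subcommands ships
at `inst/cli/minorsplice`.

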