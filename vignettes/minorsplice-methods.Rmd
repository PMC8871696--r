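---
title: "Quantifying differential minor-intron splicing in matched cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential minor-intron splicing in matched cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorsplice)
library(dplyr)
```

## The scientific question and the design

Minor (U12-type) introns are the ~0.5% of human introns excised by the minor
spliceosome. Their retention is consequential: a retained minor intron
usually destabilizes its host transcript, so the splicing efficiency of
minor introns acts as a post-transcriptional regulator of the ~600 minor
intron-containing genes (MIGs). `minorsplice` implements a matched
tumor–normal analysis of this layer: within each disease cohort, every
patient contributes one tumor and one adjacent-normal sample, and all tests
are paired, which removes between-patient baseline variation in both
retention and expression.

The pipeline stages are deliberately modular: ingestion (annotation,
coverage containers, sample sheets, matched-pair selection), PSI
quantification, per-intron paired testing with cohort-level summary,
expression analysis, activity estimation, and cross-cohort correlation. Each
stage reads and writes plain tables, so any stage can be used alone.

## PSI and its filters

For intron $i$ and sample $s$,
$\mathrm{PSI}_{is} = 100\,\frac{C^{int}_{is}}{C^{int}_{is} + C^{ej}_{is}}$,
where $C^{int}$ is the mean per-base coverage of the intron (total
alignments to the intron divided by intron length) and $C^{ej}$ the count of
spliced alignments spanning it. The length normalization makes the retained
and spliced evidence commensurable; no further length-bias correction is
applied. Three filters shape what gets tested:

* a sample yields a PSI only with at least one supporting read, spliced or
  retained — otherwise 0/0 is undefined, not zero;
* a (patient, intron) pair enters the paired table only when both tissues
  have a defined PSI;
* an intron is testable in a cohort only with at least `min_pairs = 3`
  complete pairs, and a cohort is eligible only with at least
  `min_patients = 5` matched pairs.

PSI is carried at full precision; rounding happens only in reports, because
premature rounding creates artificial rank ties in the signed-rank step.
Patients with multiple aliquots of one tissue are collapsed to the
lexicographically smallest sample id — a deterministic convention chosen
because any defensible rule must at least be reproducible.

## The paired test and its exactness

Differences `dPSI = PSI_normal − PSI_tumor` are tested per intron with the
Wilcoxon signed-rank test: zeros dropped, average ranks on ties. For
post-drop $n \le 25$ the two-sided p-value is exact by enumeration of all
$2^n$ sign assignments *conditional on the observed ranks*, computed by
dynamic programming over doubled ranks (doubling makes average ranks
integer). This convention was chosen over the classical tie-free signed-rank
distribution because paired PSI data tie readily (identical counts are
common at moderate depth), and the sign-flip enumeration remains exact in
that case, where the textbook distribution does not apply. For larger $n$
the normal approximation with tie correction and a 0.5 continuity correction
is used. Direction is classified at BH FDR < 0.05 *within* each cohort —
pooling across cohorts would let a large cohort dictate the threshold of a
small one.

The cohort summary is the minor-splicing score `n_up − n_down` plus an exact
two-sided binomial test of the up/down split at $\pi = 0.5$, BH-adjusted
across the cohorts of the run. The score is an ad hoc census statistic: it
counts significant introns rather than summing effect sizes, so it is
insensitive to a few extreme introns but sensitive to the FDR threshold.

## Activity estimation

Per tumor, activity is $\sum_i \beta_i$ with
$\beta_i = (\mu_i - T_i)/\sigma_i$, where $\mu_i,\sigma_i$ are computed
from **all** normal samples of the cohort (not only paired ones — the normal
reference should use every observation available), with the $n-1$ sample
standard deviation. Introns with $\sigma_i = 0$ or a single normal are
excluded and counted, and sums run over available introns without rescaling
to the full panel: rescaling would presume missing introns behave like
observed ones, a model the estimator does not claim. A held-out normal
scored against the remaining normals has expectation 0 by construction; the
test suite and acceptance script verify this calibration. Per-patient
activity change is the plain sum of dPSI over shared introns.

## Expression layer

Size factors are median-of-ratios: reference = per-gene geometric mean over
samples restricted to genes positive everywhere; factor = median ratio to
the reference. Note the factors are defined only up to the reference, so the
meaningful invariant is on factor *ratios* (scaling one sample's counts by
$c$ scales its factor ratio to any other sample by $c$); the implementation
is verified against DESeq2's estimator in the test suite. Differential
expression per gene set uses the same paired signed-rank engine on
normalized counts — a deliberately nonparametric choice consistent with the
splicing layer — with BH within (cohort, gene set). Fold changes use
pseudocount 1 on normalized counts: it guards zeros while leaving moderate
counts essentially untouched. MIG enrichment is a one-sided exact binomial
test of the number of significantly up MIGs against the protein-coding
background proportion; because the exact contrast is a genuine design
choice, a `significant_only` alternative (up among significant only) is
available behind a switch, with the background contrast as default.

## Correlation analyses

All correlations are Spearman on average ranks: exact permutation p by full
enumeration for $n \le 7$, the $t$ approximation on $n-2$ df otherwise. At
$\rho = \pm 1$ the $t$ branch returns $p = 0$; BH therefore accepts zero
p-values. Zero-variance vectors yield no correlation rather than a fake one.
Within cohorts, component expression is correlated with tumor activity and
component fold change with patient activity change (BH across components
within cohort); across cohorts, each gene's mean log2 fold change is
correlated with the cohort scores, BH across all genes tested — the screen
is genome-wide, so the correction must be too.

## What the generator emulates — and what it does not

`simulate_study()` draws, per (intron, sample), a negative-binomial total
informative read count (default mean 200, size 10), splits it binomially by
the true PSI, and emits the intron alignment count as
`retained_reads × intron_length` so that the mean per-base coverage equals
the retained-read count exactly. This makes the PSI estimator's sampling
distribution purely binomial and analytically checkable; the real mapping
from alignments to mean coverage is aligner-dependent and intentionally out
of scope. Tumor effects are injected as PSI-point shifts (clipped to
[0, 100]); gene counts are negative-binomial (dispersion 0.1) with
log-normal library factors and injected log2 fold changes; optional
couplings tie component expression and per-tumor PSI jitter to a latent
activity variable. The default shape — 14 cohorts, 110 minor introns, 623
MIGs among 5,000 genes, 15 components, 48 stem-signature genes, 20 pairs per
cohort — mirrors the dimensions of a pan-cancer matched-cohort study at a
scale where the whole pipeline runs in seconds.

The generator does **not** simulate reads, alignment artifacts, 3′ coverage
bias, batch effects, tumor purity, or correlated intron behavior within a
gene. Passing tests therefore demonstrate statistical correctness of the
pipeline under its stated sampling model, not robustness to every artifact
of real RNA-seq.

Two generator choices deserve emphasis:

* Baseline retention defaults to Beta(2, 8) × 100 (mean PSI 20) — minor
  introns are mostly spliced at baseline. Effect-recovery studies instead
  use Beta(10, 10) (mean 50, sd ≈ 11): a ±15-point shift is only realizable
  when baselines stay clear of the [0, 100] boundaries; at low baselines the
  shift clips at 0 and no estimator could recover it. This is a property of
  the question, not a tuning knob.
* Dropout is independent per (intron, sample), emulating the sparse
  detection of annotated minor introns in real retention catalogs (a few
  hundred annotated, far fewer detected).

## Numerical and degenerate-input conventions

All-zero difference vectors give $p = 1$; empty vectors are an error the
≥3-pair filter must prevent. Cohorts with no significant introns carry no
skew test and class `none`. Events that fail exact coordinate matching
(0-based half-open on both sides) are dropped with a logged count; duplicate
annotation coordinates abort as an ambiguous join. The whole pipeline is
deterministic given inputs and configuration, and the generator is
deterministic given its seed; the run manifest records parameters and input
digests.

## Problem sizes used in validation

The shipped validation uses a null study of 2,000 introns × 20 pairs for
type-I error, 100 replicates of a 30-intron × 50-pair cohort (8 introns
shifted −15, 4 shifted +15) for effect and score-sign recovery, 30 normals ×
60 introns for activity calibration, and 20 replicates of a 14-cohort ×
501-gene screen for the cross-cohort analysis — sizes chosen so the full
suite exercises every claim in minutes on a laptop while keeping binomial
error bands tight enough to be meaningful.

## Known limitations

The score treats every significant intron equally; cohorts of very
different pair counts have different detection power, so scores are
comparable in sign more than in magnitude. The activity estimator assumes
normal-tissue PSI is approximately location-scale stable per intron; heavy
clipping near PSI 0 or 100 compresses $\sigma_i$ and inflates $|\beta_i|$.
The HDF5 coverage dialect requires the optional rhdf5 package; the TSV long
format is the fully supported interchange.
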