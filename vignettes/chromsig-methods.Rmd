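---
title: "Methods: from chromatin profiling to a prognostic signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from chromatin profiling to a prognostic signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromsig)
```

`chromsig` turns per-sample transcription-factor peak calls, a short
stimulation time course and an expression + survival cohort into a
cross-validated prognostic gene signature. This vignette describes the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Coordinates and containers

Intervals live in `GenomicRanges` objects, i.e. the 1-based closed
convention standard across Bioconductor; BED input (0-based half-open) is
converted on read by `read_bed()` and back on write by `write_bed()`.
Keeping one internal convention and converting only at the I/O boundary is
what prevents off-by-one drift; the boundary semantics (a fragment midpoint
exactly at a region's half-open end is *outside*) are pinned by tests.
Count matrices are `SummarizedExperiment`s with regions as `rowRanges` and
library sizes in `colData`.

## Consensus peaks and occupancy

`consensus_peaks()` merges the pooled peaks of all samples by
single-linkage overlap (at least one shared base; book-ended intervals do
not merge) and scores each merged region with its *occupancy* — the number
of distinct samples contributing at least one overlapping peak, after
deduplicating identical intervals within a sample. Regions with occupancy
at or above `min_samples` (default 3, the usual "found in at least three
samples" rule for small tumor panels) are kept. Note that occupancy counts
samples *touching* the merged region; on chained merges (A overlaps B
overlaps C, A and C disjoint) this can exceed the maximum per-base
coverage. The brute-force per-base oracle in the test suite uses the same
touching-samples definition and additionally exercises landscapes without
chaining, where the two views coincide.

## Peak annotation and target genes

`annotate_peaks()` classifies each peak by its midpoint with fixed
precedence promoter > exon > intron > downstream > distal intergenic. The
promoter is the strand-oriented window 3,000 bp upstream of the TSS
(configurable; a conventional promoter-annotation default), downstream is
3,000 bp past the 3' end. `assign_peaks_to_genes()` implements the
target-gene rule: a peak is proximal to a gene when it overlaps the gene
body or the 20-kb strand-oriented window upstream of the TSS. Many-to-many
mappings are expected — several binding sites can regulate one gene, which
is why a few hundred differential sites typically compress to a shorter
gene list.

## Differential binding

The two-group comparison runs on log2 counts-per-million with a half-count
offset, `y = log2((count + 0.5)/libsize * 1e6)`; normalization is by total
library size with no input-control subtraction. Per region the pooled
within-group variance \(s^2_g\) (with \(d = n_A + n_B - 2\) df) is shrunk
toward a prior:

\[
\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},
\qquad
t_g = \frac{\Delta \bar y_g}{\tilde s_g \sqrt{1/n_A + 1/n_B}}
\]

with \(t_g\) on \(d + d_0\) df. The prior \((s_0^2, d_0)\) is estimated by
moment matching: under the scaled inverse-chi-square hierarchy the
variances are marginally \(s_0^2 F(d, d_0)\), so the sample mean and
variance of \(\{s^2_g\}\) give closed-form estimates; data without excess
variance dispersion yield \(d_0 = \infty\) (complete pooling), and fewer
than 10 regions fall back to the ordinary *t*-test because \(d_0\) cannot
be estimated stably. Forcing `prior_df = 0` recovers the ordinary
*t*-test, `prior_df = Inf` a pooled-variance z-like statistic; both limits
are tested, and the ranking agrees closely with an independent
empirical-Bayes implementation (limma) in a cross-check test. Multiplicity
is controlled by Benjamini–Hochberg at FDR < 0.10.

Robustness is assessed by *exhaustive* relabeling: every distinct
assignment of the samples into groups of the observed sizes (for the
5-vs-3 profiling design, C(8,3) = 56) is retested and the number of
significant regions recorded. A reliable signal makes the true labeling
rank first; mislabelings should find few or no regions.

## Temporal partition of target genes

Genes are first filtered on a minimum absolute log-ratio of 0.5 relative
to time 0 (the difference-from-zero rule). Candidate model profiles are
all integer level paths starting at 0 with per-step changes in
\(\{-c,\dots,c\}\) — exactly \((2c+1)^{T-1}\) of them; defaults \(c = 2\)
and \(m = 50\) representatives follow the conventional short time-series
clustering defaults. Representatives are chosen greedily to maximize the
minimum 1 − Pearson distance to the already-selected set, starting from
the flat profile, with ties broken by enumeration order — fully
deterministic. Genes go to the profile with maximal correlation (flat for
zero-variance genes; lowest profile id on ties). Significance per profile
compares the observed count to its expectation under a null that permutes
each gene's timepoint order (exhaustive for \(T! \le 5040\), otherwise
seeded draws), via a Binomial(n, expected/n) upper tail with Bonferroni
correction over the \(m\) profiles at level 0.05. Significant profiles are
classed by the sign of their mean level; genes inherit the class, and
min-change-filtered genes join the unaffected set.

Two behaviors of this scheme are worth knowing. First, the partition is
exactly mirror-symmetric under sign flip only when the profile set is
closed under negation (true for the full candidate set; a greedy subset
need not be closed, because the lowest-index tie-break can separate a
profile from its mirror). Second, when a planted class spreads over
several similar representatives, small fragments (2–4 genes) on
individually non-significant profiles remain unclassified, so recovery of
a planted rising class at noise σ = 0.15 and amplitude 1 over six
timepoints is typically 80–100% rather than exact — a property of the
per-profile significance rule, not of the implementation.

## Survival signature

Expression is probe-averaged and column-centered (`center_expression()`).
Training (`nested_cv_signature()`) is a double loop:

* **Outer**: leave-one-out. For held-out patient *p*, the inner 10-fold
  cross-validation on the remaining patients picks \(\lambda_p\)
  minimizing partial-likelihood deviance for the elastic net
  (\(\alpha = 0.5\) by default; the mixing value is a package default since
  pure lasso discards correlated co-regulated genes and pure ridge never
  selects); the active set at \(\lambda_p\) is refit by unpenalized Cox
  (Efron ties) and *p*'s prognostic index is scored with those
  coefficients. No patient's own data enters its PI.
* **Final model**: the active set of the full-data path at
  \(\bar\lambda\), the arithmetic mean of the \(\lambda_p\) (averaging on
  the original scale — the simplest reading of "average lambda"), refit by
  unpenalized Cox to give the reported per-gene coefficients.

The λ grid is 100 log-spaced values down to \(0.05\,\lambda_{max}\): a
selection-oriented grid, since the path tail below that mostly adds
near-saturated fits that are never chosen by deviance and only slow the
double loop. Folds whose active set is empty score PI = 0 and are flagged.
Unpenalized refits are only identifiable well below one covariate per
event, so active sets are capped at one covariate per three events
(keeping the largest penalized coefficients) and folds with monotone
partial likelihood fall back to the penalized coefficients; both cases are
flagged in the result. These guards matter at realistic cohort sizes
(~131 patients with ~20–30% biochemical-recurrence events).

Risk groups split at PI = 0, with PI ≤ 0 low risk (the boundary patient is
low risk). Downstream analyses go through the standard machinery:
Kaplan–Meier curves and log-rank tests (`survival`), multivariate Cox
adjustment with Gleason as ordinal, pathologic T stage ordinal-coded, nodal
status binary, and PSA log2-transformed (right-skewed, multiplicative).
The 60-month ROC treats events within the horizon as cases and patients
followed event-free beyond it as controls; patients censored early are
excluded rather than inverse-probability weighted — a simple binary ROC,
adequate for moderate censoring but biased if censoring is outcome-
dependent (a documented limitation). D'Amico groups use the standard
published thresholds (high: cT ≥ T2c or Gleason ≥ 8 or PSA > 20;
intermediate: cT2b or Gleason 7 or PSA 10–20). PCA projections fix each
component's sign by making its largest-magnitude loading positive.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their seed and export ground truth:

* `simulate_peak_landscape()` — jittered shared and group-specific peaks
  over a toy genome with gene models placed so peaks fall in promoters,
  gene bodies and distal space. Defaults mirror a 5-vs-3 two-group
  profiling design.
* `simulate_counts()` — negative-binomial counts (variance
  \(\mu + \phi\mu^2\), default \(\phi = 0.05\), baseline 50 at a 1M
  library) with planted fold changes applied to group B (half up, half
  down).
* `simulate_timecourse()` — a monotone rising profile of amplitude 1, its
  negation, and pure-noise genes, first timepoint exactly 0, Gaussian
  noise σ = 0.15 by default, over six timepoints (a 24-h stimulation
  course sampled every few hours).
* `simulate_cohort()` — standard-normal expression, exponential event
  times under a Cox model with the planted coefficients, independent
  exponential censoring calibrated by root finding to the requested
  censoring fraction (default 131 patients and 80% censoring, matching a
  typical prostatectomy training cohort; recovery tests use 30% censoring
  as their stated design). Clinical covariates are independent of
  expression by default; a confounded mode ties Gleason to the linear
  predictor for adjusted-hazard tests.

These emulate group structure, count overdispersion, temporal shape and
proportional-hazards signal — not GC or copy-number artifacts, probe
chemistry, batch effects, non-proportional hazards or informative
censoring. Passing tests therefore demonstrate that the pipeline's
inference machinery is correct and well calibrated under its stated model,
not that any particular real cohort satisfies that model.

## Problem sizes and determinism

The test suite and the acceptance script run the designs at their stated
sizes: 2,000-region count matrices for differential operating
characteristics, the 56-relabeling exhaustive permutation, 100-gene
time courses, n = 2,000 cohorts for Cox recovery and 200-patient /
100-gene cohorts for nested-CV recovery, with the leave-one-out outer loop
run in full. Every stochastic step takes an explicit seed; identical seeds
give bit-identical outputs, including the artifact bundle written by
`run_discovery()` (whose provenance record carries the parameters, seeds
and config hash). The package's entry points are its exported functions;
`run_discovery()`/`run_validation()` orchestrate the full chain and
`scripts/acceptance.R` is the reproducibility driver.
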