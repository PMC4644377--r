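# chromsig

From transcription-factor chromatin profiling to a prognostic gene
signature. `chromsig` implements, as a tested and fully seeded R pipeline,
the discovery chain used to derive survival signatures from differential
transcription-factor binding in tumors:

1. **Consensus peaks** — per-sample peak calls (BED) are merged by
   single-linkage overlap; each merged region carries an *occupancy* (number
   of samples supporting it) and regions found in at least *k* samples
   (default 3) are retained.
2. **Differential binding** — region × sample fragment counts are compared
   between two tumor groups (e.g. primary vs treatment-resistant) on
   log2 counts-per-million with an empirical-Bayes moderated *t*-statistic:
   the pooled within-group variance s²_g is shrunk toward a prior s₀² with
   d₀ prior degrees of freedom obtained by moment-matching a scaled
   inverse-chi-square distribution to the observed variances,

   &nbsp;&nbsp;&nbsp;&nbsp;s̃²_g = (d₀·s₀² + d·s²_g)/(d₀ + d),&nbsp;&nbsp;
   t_g = Δmean_g / (s̃_g·√(1/n_A + 1/n_B)),

   with Benjamini–Hochberg control at FDR < 0.10 and an exhaustive
   label-permutation robustness check (all C(n_A+n_B, n_B) relabelings).
3. **Target genes** — differential regions are coupled to genes they
   overlap, in the gene body or within 20 kb upstream of the transcription
   start site.
4. **Temporal partition** — target genes are split into
   induced / unaffected / repressed sets by short time-series profile
   clustering: integer model profiles (all (2c+1)^(T−1) level paths,
   greedy max–min representative selection), correlation-based gene
   assignment, and permutation-based profile enrichment significance with
   a minimum expression change of 0.5.
5. **Survival signature** — a nested cross-validated elastic-net Cox model
   (outer leave-one-out; inner 10-fold choosing λ by cross-validated
   partial-likelihood deviance; final active set at the average λ with an
   unpenalized Cox refit). Each patient's prognostic index
   PI = Σᵢ βᵢ·xᵢ is computed without that patient's data; PI ≤ 0 is low
   risk, PI > 0 high risk. Downstream: Kaplan–Meier curves, log-rank
   tests, multivariate adjustment for Gleason score / T stage / nodal
   status / PSA, 5-year ROC AUC, D'Amico cross-tabulation and PCA
   projection of the signature genes.

A seeded synthetic-data module (`simulate_peak_landscape()`,
`simulate_counts()`, `simulate_timecourse()`, `simulate_cohort()`) emulates
every input with exported ground truth, so the whole pipeline runs and is
benchmarked without any external download.

## Worked example

```r
library(chromsig)

res <- run_discovery(pipeline_config(seed = 1, n_patients = 60,
                                     n_genes = 30, censoring_rate = 0.5,
                                     signature = setNames(c(1, -1, 0.8, -0.8),
                                                          paste0("g", 1:4))))
length(res$consensus)                        # 70 consensus regions
sum(res$differential$direction != "ns")      # 32 differential regions
res$permutations$rank                        # 1: true labeling ranks first
lengths(res$temporal$sets)[c("up", "flat", "down")]  # 40 / 50 / 10
res$signature$model
#> signature_model: 6 genes (alpha = 0.5 , lambda_bar = ...)
logrank_test(res$cohort$time, res$cohort$event, res$signature$risk)$p
#> 0.005 (cross-validated risk split on the 60-patient synthetic cohort)
```

The consensus regions, differential table, permutation report, target-gene
lists, temporal sets, per-patient prognostic indices and the signature
model (JSON) are all written to `out_dir` when one is given, along with a
provenance record (parameters, seeds, config hash). `run_validation()`
applies a trained model to an independent cohort and reports the risk-group
Kaplan–Meier curves, log-rank p, horizon AUC, D'Amico cross-tabulation and
PCA scores.

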