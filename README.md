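# tissuehet

Tissue heterogeneity — expression signal from cells of other origins than
the annotated tissue, caused by infiltration, contamination during
dissection, or outright mislabelling — is a pervasive and mostly silent
confounder in bulk gene expression data. `tissuehet` is an R package for
detecting it: it scans every sample of a corpus with tissue-specific gene
signatures, separates *moderate* heterogeneity (a foreign tissue signature
is present while the expected one is still detected) from *severe*
heterogeneity (the expected signature is lost, suggesting a mislabel or
gross mishandling), and estimates per-tissue prevalence with bootstrap
confidence intervals. It is aimed at anyone curating or mining bulk
transcriptome collections — microarray or RNA-seq — who needs a
quality-control gate before downstream analysis.

## Method

The core primitive is a one-sided Wilcoxon–Mann–Whitney test applied
*within one sample*: for signature gene set *S* and background genes *B*
of a sample, the rank sum of the signature genes

  U = Σ_{g∈S} rank(x_g) − |S|(|S|+1)/2

is compared against its permutation distribution (normal approximation
with tie-corrected variance and continuity correction at corpus scale,
exact enumeration for small gene universes), giving a p-value for
"signature genes rank higher than background". Because only within-sample
ranks enter, the test is invariant to any monotone per-sample transform —
no cross-sample normalisation is needed.

Detection proceeds in five steps for a sample *s* annotated as tissue *t*,
with query signatures *k* and the tissue's reference signature:

1. compute p_query for all (sample, query signature) pairs and
   Benjamini–Hochberg-adjust them jointly; q ≥ τ (τ = 0.01) means *not
   heterogeneous*;
2. per (t, k) pair, fit a robust (Huber) line of |log10 p_query| against
   |log10 p_ref| over all samples annotated t;
3. exclude pairs with slope ≥ 0.01 — such query signatures merely track
   the tissue's own physiology;
4. flagged samples are *severe* when additionally unadjusted
   p_ref > 0.05 (the annotated tissue's own signature is not detected),
   otherwise *moderate*;
5. per tissue, report the flagged fraction with a percentile bootstrap
   confidence interval (1000 resamples).

Tissue signatures can be supplied as GMT files or generated from a
labelled expression atlas with a Gini-index criterion (a gene enters a
tissue's signature when its per-tissue median profile is sufficiently
concentrated, Gini ≥ 0.8, and the tissue ranks among the gene's top
expressers) and cross-validated on an independent dataset.

A seeded synthetic-corpus generator with full ground truth (tissue
programs, contamination mixtures, mislabels, log-normal noise) backs the
test suite and lets you measure sensitivity and specificity of the whole
pipeline under known conditions.

## Worked example

```r
library(tissuehet)

res <- run_pipeline(run_config(
  output_dir = "demo_run",
  detection  = detection_config(rng_seed = 42),
  sim        = sim_config(samples_per_tissue = 50, rng_seed = 42),
  verbose    = FALSE
))
res$detection
#> Heterogeneity detection over 450 samples
#>   none: 400  moderate: 41  severe: 9
#>   excluded signature pairs: 18 of 72

tissue_fractions(res$detection)
#> # A tibble: 9 x 7
#>   tissue n_samples n_moderate_or_severe n_severe fraction ci_low ci_high
#>   <chr>      <int>                <int>    <int>    <dbl>  <dbl>   <dbl>
#> 1 blood         50                    6        1     0.12   0.04    0.22
#> 2 brain         50                    8        2     0.16   0.06    0.28
#> 3 heart         50                    8        1     0.16   0.06    0.26
#> # ... 6 more rows

res$truth_performance[, c("sensitivity", "specificity", "severe_given_mislabel")]
#> # A tibble: 1 x 3
#>   sensitivity specificity severe_given_mislabel
#>         <dbl>       <dbl>                 <dbl>
#> 1       0.926           1                     1
```

The simulated corpus (450 samples, 9 tissues) contains 45 contamination
mixtures and 9 mislabels; the run flags 50 samples (41 moderate, 9
severe), i.e. 92.6% of the planted heterogeneous samples are recovered,
no pure sample is flagged, and every mislabel is classified severe. The
output directory holds the full bundle — per-sample calls, excluded
signature pairs, per-tissue summaries with bootstrap CIs, the tissue
confusion matrix and a human-readable `report.md`.

`autoplot()` methods are available for the per-tissue summary, the
confusion matrix and signature cross-validation results; `tidy()` and
`glance()` follow broom conventions. A thin command-line wrapper with
`simulate` / `filter` / `enrich` / `detect` / `report` / `run-all`
subcommands ships in `inst/cli/tissuehet.R`.

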