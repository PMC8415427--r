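---
title: "Detecting tissue heterogeneity in bulk expression corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tissue heterogeneity in bulk expression corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuehet)
```

## The problem

A bulk expression profile is an average over the cells that ended up in the
tube. When some of those cells come from a different origin than the
annotated tissue — infiltrating blood or immune cells, a sliver of a
proximal organ caught during dissection, or a plain sample swap — the
profile carries foreign tissue programs. Downstream, this inflates variance,
weakens signals and can invalidate conclusions, and unlike batch effects it
is invisible to per-study normalisation. `tissuehet` detects such *tissue
heterogeneity* sample by sample and distinguishes two regimes:

* **moderate** — a foreign tissue's signature is significantly enriched
  while the annotated tissue's own signature is still clearly present;
  typical of infiltration or partial contamination;
* **severe** — the foreign signature is enriched *and* the annotated
  tissue's signature is not detected; typical of mislabelling or gross
  mishandling.

## Per-sample rank enrichment

Every decision rests on a one-sided Wilcoxon–Mann–Whitney test computed
within a single sample: do the genes of a signature rank higher in this
sample's expression than the remaining (background) genes? Using only
within-sample ranks has two consequences that shape the whole design:

* any strictly increasing per-sample transform (log, quantile scaling,
  unit changes) leaves all p-values unchanged, so corpora processed with
  different pipelines are comparable without renormalisation;
* per-gene–centred matrices destroy the within-sample ordering and
  *cannot* be used — the corpus filter rejects studies that look per-gene
  normalised (see below).

Ties get midranks. The default p-value path is the normal approximation
with tie-corrected variance and a continuity correction; for gene
universes of at most 25 genes the implementation switches to exact
enumeration of the permutation distribution (a subset-sum dynamic program
over doubled midranks, exact also under ties). Two numerical notes:

* the approximation tracks the exact tail to within about 0.2 in
  log10 p for continuous-valued data at any universe size, but degrades
  for *heavily tied* values on tiny universes (deviations up to ~0.4 in
  log10 p at 12 genes with a 5-symbol value alphabet) — that regime is
  exactly why the exact-mode cutoff exists, and real expression values
  are effectively continuous;
* p-values are floored at 1e-300 before any |log10 p| transform so that
  numeric underflow cannot produce infinities in the exclusion fits.

## Signatures: generation and cross-validation

Signatures can be read from GMT files (`read_gmt()`), with query and
reference roles. They can also be generated from a labelled atlas with
`generate_signatures()`: a gene's *tissue profile* is its median
expression per tissue; the gene enters tissue *t*'s signature when

* the Gini index of its profile is at least `gini_min` (default 0.8), and
* *t* is among the gene's `rank_max` (default 3) highest-expressing
  tissues, ties at the boundary included (min-rank, deterministic).

Signatures are truncated to `max_genes` (default 200) by descending
profile value. Both criteria are scale-free, so regenerating from a
rescaled matrix gives identical signatures. Genes with an all-zero profile
are skipped; aggregation uses the median for robustness to outlier
samples. Defaults follow the conventions of established signature
toolkits; all four knobs are exposed because the attainable Gini depends
on the data: a single-tissue elevation of fold *f* over a non-zero
baseline across *T* tissues has Gini (T−1)(f−1)/(T(T−1+f)), e.g. 0.81 for
f = 100 and T = 9, but only 0.65 for T = 3. High thresholds therefore
implicitly demand near-zero off-tissue expression, which is what true
tissue-restricted genes show.

`crossvalidate_signatures()` scores signatures on an independent labelled
dataset: each sample's *top hit* is the signature with the smallest
p-value, and per-tissue sensitivity is the fraction of samples whose
top-hit tissue matches the annotation. The confusion matrix and median
score matrix support manual review before trusting a signature as a
*reference*.

## The five-step detector

For a sample *s* annotated as tissue *t*, with q-values from a
Benjamini–Hochberg adjustment over all (sample, query-signature) pairs of
the run (a per-tissue adjustment family is available via
`detection_config(bh_scope = "per_tissue")`; reference-signature
self-tests are not part of the family):

1. if no query signature reaches q < τ (default τ = 0.01), *s* is not
   heterogeneous;
2. for every (t, query k) pair, a robust line of |log10 p_query| against
   |log10 p_ref| is fitted over *all* samples annotated t — including
   unflagged ones;
3. pairs with slope ≥ 0.01 are excluded: their query signature rises and
   falls with the tissue's own reference signature, which marks
   physiological relatedness rather than contamination. Exclusions are
   recorded and shown distinctly in the confusion matrix;
4. a flagged sample is *severe* if its unadjusted p_ref > 0.05 (severity
   is a property of the sample — there is one reference p-value per
   sample — not of individual triggering signatures), else *moderate*;
5. per-tissue fractions of flagged samples are reported with percentile
   bootstrap confidence intervals (default 1000 resamples, level 0.95,
   seeded and recorded).

Query signatures mapped to the sample's own annotated tissue never count
as evidence — otherwise every sample would trivially "detect" itself.
The robust fit is Huber M-estimation by iteratively reweighted least
squares (tuning constant 1.345, scale re-estimated each iteration as the
MAD rescaled for normal consistency, convergence at 1e-8 or 50
iterations); a constant-x design yields slope 0 by contract, and fewer
than 3 samples is an error. The exclusion fits pool all studies of a
tissue; a per-study variant was considered and rejected because small
studies would make the slope estimate meaningless.

Two deliberate scope choices: the BH family is the whole run, matching
the corpus-level framing of the method (millions of pairs), and the
bootstrap interval is the percentile flavour — simple, respects the
[0, 1] range, and exact in the degenerate all-zero case.

## The synthetic corpus generator

`simulate_corpus()` emulates the statistical structure the detector
assumes, with full ground truth:

* a log-normal baseline per gene (meanlog 3, sdlog 1 on the natural
  scale — a right-skewed abundance distribution spanning several orders
  of magnitude, as in real intensity or expression-level data);
* disjoint blocks of signature genes per tissue, elevated
  `fold_change`-fold in their tissue's samples (default 100, typical of
  strongly tissue-restricted genes and large enough that the 9-tissue
  profile clears the default Gini threshold); an `overlap_fraction`
  parameter can elevate shared genes in neighbouring tissues to
  manufacture correlated signatures for exclusion-logic tests;
* contamination as *linear mixing on the natural scale before noise* —
  (1−λ)·own profile + λ·contaminant profile — matching the physical
  picture of cell admixture (log-scale mixing was rejected as
  non-physical); default 10% of samples at λ = 0.3;
* mislabels as samples carrying another tissue's full profile under the
  wrong annotation (default 2%), disjoint from the mixtures;
* multiplicative log-normal noise applied last (sd 0.3 on the log
  scale).

Defaults are the package's reference study conditions. What the generator
does **not** emulate: probe-level microarray artifacts, count-based
sampling noise, batch effects, partial-transcriptome platforms,
continuous gradients of infiltration, or correlated gene–gene noise.
Passing the test suite therefore demonstrates the pipeline's correctness
and its operating characteristics under the stated model, not its error
rates on any particular public repository — prevalence estimates on real
corpora depend on the repository snapshot, curation and signature
quality.

When the pipeline generates signatures from synthetic training corpora
(two extra clean corpora derived from the simulation seed, so signatures
are never fitted on the evaluated samples), it uses `rank_max = 1` and
`gini_min = 0.5`: with disjoint planted programs the owning tissue is the
unique top tissue, and looser ranks would only admit foreign genes via
baseline-noise tie-breaks, coupling query signatures to foreign
references and triggering wholesale exclusions.

## Corpus filtering

`filter_corpus()` applies, in order: (1) drop samples whose free-text
tissue does not normalise (lowercase, whitespace collapse, trailing
punctuation stripped — no fuzzy matching) to a controlled-vocabulary
term; (2) drop samples of tissues without a reference signature; (3) drop
whole studies flagged as per-gene normalised — more than 25% negative
entries or more than half of gene rows with |row mean| below 1% of the
study's interdecile range; (4) optionally drop studies below a size
floor (default: none). Every rule reports its count, the counts sum to
the dropped total, and the filter is idempotent.

## Validation at a glance

The test suite checks each stage against independent oracles — exhaustive
enumeration for the rank test, the mean-absolute-difference double loop
for the Gini index, the literal step-up recursion for BH, `MASS::rlm` for
the Huber line, `wilcox.test` for tie-free exact p-values — plus
end-to-end runs on seeded corpora of about 2000 samples across 9 tissues
(222 per tissue): a null corpus for false-discovery behaviour, the
default contaminated corpus for sensitivity and severity separation, a
correlated-signature construction for the exclusion logic, 500 simulated
tissues of 200 samples for bootstrap coverage, and an independent-corpus
pair for signature transfer. These sizes keep the whole suite within a
few minutes on a single core while leaving the binomial noise on every
estimated rate well inside the asserted margins.

## Limitations

* Symbol-level gene matching only: probe-to-symbol and ortholog mapping
  are input responsibilities.
* The exclusion rule trades sensitivity for specificity: genuinely
  contaminated samples of a tissue pair that is also physiologically
  correlated are not counted.
* The severity rule inherits the reference signature's quality — a weak
  reference inflates severe calls; that is why references should be
  cross-validated before use.
* Slope estimates need enough samples per tissue; with very few samples
  the threshold of 0.01 is within estimation noise and exclusions become
  erratic (the implementation refuses to fit below 3 samples, but tens
  of samples per tissue are a practical minimum).
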