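---
title: "Cell-type enrichment estimation from bulk transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type enrichment estimation from bulk transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctenrich)
```

## The model

`ctenrich` scores bulk transcriptomes for the presence of reference cell
types by marker-gene enrichment. The method deliberately does **not**
estimate cell fractions: its output — an odds ratio per (sample, cell
type) — is a relative score whose meaning comes from comparing samples
scored together. This buys robustness (no linearity assumption between
signal and cell fraction, no need for the references to span the whole
tissue) at the price of absolute interpretability.

The pipeline has three stages.

**1. Signatures from a reference atlas.** The atlas is a gene × lineage
matrix of non-negative expression; technical replicates are averaged
first (`average_replicates()`). For gene $g$ with atlas row
$x_{g,\cdot}$ over $N$ lineages, the relative expression is
$p_{(l|g)} = x_{g,l} / \sum_{l'} x_{g,l'}$ and the specificity index is
the entropy-based statistic

$$S_{(l|g)} \;=\; -\sum_{l'=1}^{N} p_{(l'|g)}\log_2 p_{(l'|g)} \;-\; \log_2 p_{(l|g)} \;=\; H_g - \log_2 p_{(l|g)}.$$

$S$ is minimized, at 0, by genes expressed exclusively in lineage $l$;
a uniformly expressed gene scores $2\log_2 N$ for every lineage; genes
not expressed in $l$ at all score $+\infty$. `build_signatures()`
therefore ranks genes by **ascending** $S$ and keeps the top
$m = 80$ per lineage. The phrase "highest specificity" in parts of the
literature refers to the most *specific* genes, i.e. the smallest values
of this statistic; ranking by descending $S$ would select the most
promiscuously expressed genes instead. Because the direction is a
semantic trap, it is exposed as `rank_by` (default `"ascending"`), and
the descending option exists only for diagnostic use.

**2. Scoring against a Monte-Carlo null.** For each query sample, an
expressed-gene set $E$ is formed by thresholding; the observed statistic
per lineage is $k_{obs} = |signature \cap E|$. Chance enrichment is
estimated empirically: $B = 1000$ lists of $m$ genes drawn uniformly
without replacement from the reference gene universe $U$, giving a mean
overlap $\bar k_{null}$ whose analytic value is $m\,|E \cap U|/|U|$
(hypergeometric mean; the package asserts agreement in its tests). A
two-sided Fisher's exact test on
$[[k_{obs}, m-k_{obs}], [k_{null}, m-k_{null}]]$ yields the p-value and
odds ratio.

**3. Intersample comparison.** Per lineage, cohort odds ratios are
min-max rescaled to $[0,1]$ (`normalize_odds_ratios()`); group contrasts
use two-tailed Student's t-tests (pooled-variance unpaired, or paired
differences) with Benjamini–Hochberg correction across lineages
(`compare_groups()`).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `signature_size` (m) | 80 | markers per lineage; smaller values speed up scaled-down runs and weaken signatures |
| `n_lists` (B) | 1000 | Monte-Carlo lists per sample null; Monte-Carlo SE of $\bar k_{null}$ scales as $B^{-1/2}$ |
| `threshold`, `mode` | 1, `"absolute"` | expressed-gene gate; absolute value > t suits TPM-like units. For arbitrary-scale intensity data use `mode = "quantile"` with t = 0.5 (upper half). The threshold is always recorded in the result metadata |
| `universe` | atlas genes | the null-model gene universe; `"query"` restricts to genes measured in the query |
| `seed` | 42 | drives all null draws; recorded in outputs |
| `alpha` | 0.05 | significance level defining the spike-in limit of detection |

Two-sidedness is used throughout (Fisher and t), matching standard
practice for these designs. The odds ratio is the sample (cross-product)
ratio with the Haldane–Anscombe +0.5 correction when a cell is zero —
not the conditional-MLE estimate `stats::fisher.test()` reports — because
the score is used descriptively across samples and must be defined,
finite and monotone in $k_{obs}$ even at the boundary.

## Numerical and design choices

- **Integerized null.** Fisher's test needs integer counts, so
  $\bar k_{null}$ enters the table rounded half away from zero; the
  real-valued mean is also reported (`null_mean`).
- **Per-sample null seeding.** Each sample's null draws are seeded by the
  base seed plus a content hash of its expressed set. Identical samples
  therefore receive identical draws (and identical rows), while distinct
  samples get independent draws, and a sample's score never depends on
  cohort order or composition — which keeps paired designs (spike-in)
  exactly paired at $f = 0$.
- **Ties in signature ranking** break by higher expression in the target
  lineage, then lexicographic gene identifier (radix order), so signature
  files are byte-identical across platforms.
- **Degenerate cases.** Zero atlas rows are excluded from candidacy;
  an empty expressed set scores $p = 1$, OR $= 1$ everywhere; a lineage
  with constant cohort odds ratios normalizes to 0; all-zero paired
  differences give $t = 0$, $p = 1$ (and zero-variance nonzero
  differences $p = 0$).
- **Normalization cohort** is the set of samples scored in one call.
  Min-max stretches pure noise to the full $[0,1]$ range for lineages
  with no true signal anywhere in the cohort; interpretation of "which
  lineage is top" is only meaningful when each lineage's column is
  anchored by genuine variation (see the positive-control design below).
- **Spike-in mixing** is linear in normalized expression space: both
  profiles are renormalized to a common total $T = 10^6$ over the gene
  union, then mixed as $(1-f)\,b + f\,s$. $f$ is thus an RNA-mass
  fraction under an equal-RNA-per-cell assumption; mass is conserved to
  within $10^{-6}T$ by construction. The background cohort size is a
  parameter (validation here uses 50 and below; cohorts of ~100 are
  typical in practice).

## The synthetic-data generator

`simulate_atlas()` emulates a right-skewed expression atlas: baseline
levels are log-normal (meanlog 3, sdlog 1); each lineage receives
exclusive marker genes at `fold_change` (default 20) times baseline;
replicates get multiplicative log-normal noise with unit mean
(meanlog $-\sigma^2/2$), so planted expectations are exact. The default
study conditions are 6 lineages × 5000 genes, 120 markers per lineage,
3 replicates, fold change 20, $\sigma = 0.3$ — rich enough that an
80-gene signature can be fully planted, and small enough that a full
scoring run takes a fraction of a second.

`simulate_mixture()` builds query samples from the *noiseless* lineage
means (normalized to sum 1, scaled to $T$), with one round of unit-mean
log-normal noise at the sample level, so the ground-truth weights are
exact in expectation. A marker-free pseudo-lineage `"background"` (the
baseline vector without any fold change) can carry weight; it emulates
bulk tissue whose dominant content is not represented by any atlas
lineage — the situation in which rare-cell detection actually operates.

Positive-control recovery is evaluated the way validation heatmaps are
built: one sample per lineage, each 95% background + 5% of that lineage,
scored as one cohort. Every lineage column of the normalized-OR matrix is
then anchored by its own positive control, and the planted lineage is
required to *strictly* top its sample's scores. With a single planted
sample in a cohort, by contrast, all other lineage columns are pure
noise stretched to $[0,1]$ and "top score" carries no information — a
direct consequence of min-max normalization worth remembering when
interpreting real heatmaps.

What the generator does **not** model: gene length/GC bias, count noise,
correlated marker co-expression, shared markers between related lineages,
or compositional distortion. Passing tests on synthetic data therefore
demonstrate correctness of the estimator's mechanics and its sensitivity
under idealized signal, not performance on any real tissue.

## Problem sizes used in validation

The shipped tests run the default 6 × 5000 synthetic atlas; planted
recovery uses 100 cohorts of 6 samples at $B = 1000$; the spike-in power
check uses 50 background samples over fractions
$\{0, 0.001, 0.005, 0.01, 0.05\}$ with 10 seeds; the false-positive-rate
check uses 200 repetitions of 8 paired samples at reduced $B$. These
sizes were chosen so the full suite completes in a few minutes while the
Monte-Carlo assertions retain comfortable margins (4 standard errors for
the null mean; ±3 binomial standard deviations for the type-I rate).

## Known limitations

- Odds ratios are relative scores; they cannot be compared across runs
  with different settings, cohorts or signature maps, and they are not
  cell fractions.
- One null model per sample is shared across lineages, so lineage scores
  within a sample are not independent.
- The expressed-gene threshold is a modeling choice the data cannot fully
  determine; results should be reported with the recorded threshold
  metadata.
- With very small universes or extreme thresholds the integerized null
  can sit at 0 or $m$, where the Fisher table loses resolution.
- Signature quality is bounded by the atlas: lineages sharing biology
  (e.g. closely related progenitor stages) share markers, and their
  scores will correlate.

```{r example, eval = FALSE}
# A minimal end-to-end run on synthetic data:
sim   <- simulate_atlas(seed = 1)
atlas <- average_replicates(sim$expression, sim$replicate_map)
sig   <- build_signatures(atlas)
mix   <- simulate_mixture(sim, c(background = 0.95, L1 = 0.05),
                          n_samples = 4, seed = 2)
res   <- score_cohort(mix, sig, threshold = 0.5, mode = "quantile")
autoplot(res)
```
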