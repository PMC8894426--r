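---
title: "Discriminating clinical phenotypes from two-matrix untargeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating clinical phenotypes from two-matrix untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

PTEN hamartoma tumor syndrome (PHTS) is caused by germline mutations in
the *PTEN* tumor suppressor and presents with two strikingly different
phenotypes: cancers (thyroid cancer having the earliest onset) and
neurodevelopmental conditions such as autism spectrum disorder and
developmental delay (ASD/DD). Whether an individual carrier will develop
one, the other, or both is currently unpredictable. One line of attack
is metabolomic: profile patient-derived lymphoblastoid cell lines (the
"cells" matrix) together with their spent growth media (the "media"
matrix, a secretome readout) by untargeted mass spectrometry, and ask
whether metabolite abundances, cells/media ratios, or coordinated
pair-wise ratio patterns ("metabotypes") separate carriers with ASD/DD
from carriers with cancer.

`metabophen` implements that analysis end to end as tested, reusable
code: a synthetic-cohort generator standing in for patient data, the
normalization chain, covariate-adjusted moderated differential
abundance, the two ratio analyses, correlation-block and clustering
analyses, and leave-one-out cross-validated (LOOCV) LogitBoost
classification with three feature-reduction variants.

## Study design emulated by the generator

The design is a matched three-group comparison: ASD/DD without cancer,
cancer without ASD/DD, and both phenotypes, with `n = 10` per group,
identical sex composition (7 female / 3 male per group by default), and
ages drawn from a common law so the groups are exchangeable in age.
`generate_cohort()` reproduces this design and `verify_matching()`
certifies it with Fisher's exact test on the group-by-sex table (p = 1
for a perfectly matched design) and the Kruskal–Wallis rank sum test on
age. Instrument batches are assigned round-robin within group so batch
can never masquerade as a phenotype effect.

`generate_tables()` draws raw peak areas as

\[
x_{gis} = \exp\big(\mu_{g} + b_{g,\mathrm{batch}(i)} + u_i + \delta_{g,\mathrm{group}(i)} + \varepsilon_{gi}\big),
\]

with log-normal per-metabolite baselines \(\mu_g \sim N(10, 2^2)\)
(magnitude is irrelevant after normalization), per-(metabolite, batch)
multiplicative instrument effects \(b \sim N(0, \texttt{batch\_sd}^2)\)
(default 0.3), independent observation noise \(\varepsilon \sim N(0,
\texttt{noise\_sd}^2)\) (default 0.3), optional planted group effects
\(\delta\), and an optional per-sample loading factor \(u_i \sim N(0,
\texttt{sample\_sd}^2)\) shared between a sample's cells and media
measurement. Raw cell values additionally scale with a log-normal
protein concentration (20% CV), which the protein-normalization step
removes again. Missingness is left-censoring at the per-metabolite
`censor_fraction` quantile (default 5%), matching the detection-limit
interpretation that justifies minimum-value imputation downstream.
Default metabolite counts mirror the study scale: 645 cell metabolites,
489 media metabolites, 386 shared.

Two generator choices deserve comment:

* **`sample_sd` defaults to 0.** With the default, samples are
  independent and the moderated pipeline's null p-values are uniform
  (this is verified by a Kolmogorov–Smirnov test over 2,000 features).
  Setting `sample_sd > 0` emulates the paired technical variation
  (loading, dilution, harvest density) that is common to every
  metabolite of a sample. That component is exactly what ratio features
  cancel and what single-metabolite analysis must absorb as extra
  variance, so the power comparisons between the ratio arm and the
  single-metabolite arm are run at `sample_sd = 0.45` — about 1.5 times
  the observation noise, a realistic share for cell-culture metabolomics.
* **Planted "2-SD" effects** are defined against the total
  per-observation log standard deviation
  \(\sqrt{\texttt{noise\_sd}^2 + \texttt{sample\_sd}^2}\) (= 0.541 under
  the paired-noise conditions, i.e. a planted log effect of 1.08, a
  ~3-fold abundance change). Recovery simulations use tables at the
  study scale (30 samples, 645/489/386 metabolites, 20 replicates).

What the generator does **not** emulate: chromatographic drift, isotope
patterns, correlated metabolite modules from real biochemistry, spectral
library mis-identification, or non-log-normal heavy tails. Passing
recovery tests therefore demonstrate that the code implements its
contracts, not that identical power would be achieved on real cohorts.

## Normalization

`normalize_matrix()` composes the chain exactly as the measurement
provider defines it:

1. **Batch median scaling** — per metabolite, observed values in each
   instrument batch are divided by the batch median, giving every
   (metabolite, batch) group median 1. Medians see observed values only;
   a (metabolite, batch) group with no observed value is an error rather
   than a silent guess.
2. **Protein normalization** (cells only) — each sample's values are
   divided by its protein concentration, then each metabolite is
   re-scaled to overall median 1. The re-scaling median is computed
   globally per metabolite (not per batch); this choice is recorded in
   the run manifest.
3. **Minimum-value imputation** — each missing entry receives its
   metabolite's minimum observed scaled value across all batches, and
   the imputation mask is carried alongside the data.
4. **Natural log, center-scale** — log-transformed values are centered
   to mean 0 and scaled to sample standard deviation (n−1 denominator) 1
   per metabolite. Metabolites that end up constant (e.g. fully imputed)
   are dropped with a warning rather than erroring; the count is logged.

One numerical subtlety governs what feeds what downstream.
**Differential testing consumes the log-scale values, not the
center-scaled values.** The per-feature t statistic is scale invariant,
so single-feature inference is identical either way; but the
empirical-Bayes variance pooling is not. Dividing each feature by its
own estimated standard deviation ties the residual variance to the
fit's R², which couples the "variance" to the "effect" and destroys the
calibration of the pooled test (we observed decisively non-uniform null
p-values before making this choice). Center-scaled values are the right
input for clustering and classification, where features must be
comparable, and that is where they are used.

## Differential abundance with variance moderation

For each feature the model is ordinary least squares on
`intercept + group + age_at_consent + sex` (two-group contrast) or the
two group indicators (three-group omnibus), fitted to all features at
once through one QR decomposition. Empirical-Bayes moderation follows
the closed-form moment-matching estimator on log variances: with
\(e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)\),

\[
\operatorname{trigamma}(d_0/2) = \operatorname{var}(e) - \operatorname{trigamma}(d_g/2),
\]

solved by monotone Newton iteration (tolerance 1e-10, at most 100
iterations), and \(s_0^2\) from the first moment. When the observed log
variances are no more dispersed than a chi-square implies, \(d_0 =
\infty\) and \(s_0^2\) is the bias-corrected geometric-mean pooled
variance. The moderated statistic uses
\(\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)\) with a Student-t
reference on \(d_0 + d_g\) degrees of freedom (normal when infinite).
The implementation is checked in the test suite against limma's
`eBayes` to 1e-8 on both the two-group t and the omnibus F — limma is
the cross-check, never the implementation. Multiple testing uses
Benjamini–Hochberg (the cited toolchain's default; the study states only
"multiple testing corrected"), with significance at adjusted p < 0.05.

Two-sample Welch t and Wilcoxon rank-sum tests are exposed for
unadjusted pairwise comparisons; Welch is used because the equal-variance
assumption buys nothing here and the study does not specify.

A note on the null-FDR acceptance check: under a continuous global null
the BH procedure satisfies \(E[\mathrm{FDP}] = \alpha\) *exactly*, so
the sample mean over 200 simulations lands above 0.05 about half the
time no matter how correct the code is. The test therefore compares the
mean against the bound plus its one-sided two-standard-error Monte-Carlo
margin, and the acceptance script reports the measured mean as-is.

## Ratio features

Both ratio analyses are computed as differences of natural-log values
*before* center-scaling (a difference of logs is a log ratio; scaling
first would destroy that interpretation), and the resulting features are
then center-scaled themselves for testing, clustering and
classification.

* `cell_media_ratios()` — one feature per metabolite detected in both
  matrices (386 at study scale), `log(cells) − log(media)` per sample.
* `pairwise_panel_ratios()` — the metabotyping arm: all unordered pairs
  of a prioritized panel (43 amino-acid/mitochondrial-energetics
  metabolites in the study) detected in a matrix; 38 detected
  metabolites give 703 ratio tests, 39 give 741, i.e. \(n(n-1)/2\). Only
  the lexicographically ordered pair is stored; reversing a pair negates
  the feature but leaves every test p-value unchanged.

Ratio features are invariant to any per-sample global log shift, which
single-metabolite features are not — this is the mechanistic reason the
ratio arm can recover coordinated alterations at half-effect-per-member
that the single-metabolite arm misses, and the property-based tests
verify both halves of that claim.

## Correlation blocks and clustering

`correlation_matrix()` reports pairwise Pearson (default; the study
does not name the method — Spearman is available by argument)
correlations with two-sided p-values and a significance mask at p <
0.05, mirroring correlation plots that draw only significant entries.
`detect_negative_blocks()` formalizes the visual "negative correlation
block": features are ordered by complete-linkage clustering of
correlation distance (1 − r) and cut at distance 1 (r = 0), and every
pair of clusters with at least `min_block_size` (default 3) members on
both sides whose mean significant correlation is at most
`mean_r_threshold` (default −0.3) is reported, ranked by |mean r|.

`hcluster_samples()` clusters samples with distance 1 − Pearson
correlation between feature profiles and complete linkage;
`misclassified_samples()` cuts at k groups, assigns each cluster its
majority phenotype (ties break toward "not misclassified") and returns
the disagreeing samples — the operation behind "separates the groups
with the exception of two patients" statements.

## Classification

`fit_logitboost()` implements additive logistic boosting with decision
stumps: per iteration, working responses \(z_i = (y^*_i - p_i)/(p_i(1 -
p_i))\) and weights \(w_i = p_i(1-p_i)\) (probabilities clipped to
\([10^{-4}, 1-10^{-4}]\)), a weighted least-squares stump over all
(feature, midpoint-threshold) candidates with ties broken by (feature
index, threshold) for determinism, half the fitted value added to the
committee, and the logistic link updates the probabilities. Multiclass
tasks fit one-vs-rest committees.

`loocv()` predicts each sample from a committee trained on the others.
The iteration count is selected from `logitboost_iter_grid` (default
{11, 21, 31}; the study names no count) by best LOOCV accuracy, ties to
the smallest. Two modes matter:

* **paper mode** (default): feature significance, correlation pruning
  and PCA are fitted once on all samples before cross-validation. This
  mirrors the original procedure and is optimistically biased — the
  report header says so.
* **nested mode**: every transformation is refitted inside each fold;
  use it for honest generalization estimates.

Three feature-extraction variants reproduce the performance-table
layout: all significant features; `remove_linear_correlated()` (exact
linear combinations removed by rank-revealing pivoted QR at tolerance
1e-8, then greedy pruning of pairs with |r| ≥ 0.90, dropping the member
with the larger mean absolute correlation); and `pca_reduce()` keeping
the fewest components reaching 95% cumulative variance (the study
reports component counts but not the retention rule; the threshold is
configurable and achieved counts are logged). `confusion_report()`
returns the confusion matrix, overall accuracy with its exact
Clopper–Pearson 95% interval, the no-information rate, the one-sided
exact binomial p-value against the NIR, and sensitivity/specificity for
the positive class (CANCER by default, per the study's convention) or
per class one-vs-rest for three groups. All metrics are recomputable
from the emitted confusion matrix; intervals always derive from the
actual prediction count.

## Pipeline, determinism, problem sizes

`run_all()` executes the four analysis arms off a single normalization
pass per matrix, writes every artifact as deterministic TSV (17
significant digits, fixed column order), and ends with a manifest
listing config, seed, and an md5 hash per file; re-running with the same
config and seed reproduces identical hashes. The run seed fans out to
per-stage substreams so each stage is reproducible independently of
execution order. Unit and property tests run on reduced tables (30
samples, 40–60 metabolites) for speed; calibration and recovery
simulations use 2,000-feature null tables, 200 null replicates
(30 × 500), 5,000-feature prior recovery, 20 study-scale planted
replicates, and 100 label permutations — sizes at which the Monte-Carlo
error is comfortably below the margins being asserted.

## Known limitations

* Paper-mode LOOCV is optimistically biased by design (it reproduces
  the study's procedure); nested mode exists but is not the default.
* The blank matrix is normalized and carried as a negative control
  only; no background subtraction is attempted.
* Spearman p-values use the t approximation of the rank null, not the
  exact permutation distribution.
* The generator's independence assumptions (no metabolite-module
  correlation beyond the shared sample factor) make planted-effect
  power estimates optimistic relative to real cohorts.
* Three-group sensitivity/specificity are reported per class
  (one-vs-rest); the study does not state its averaging convention.
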