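---
title: "Benchmarking differential abundance calls on relative versus absolute counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential abundance calls on relative versus absolute counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sequence counting — bulk RNA-seq, single-cell RNA-seq, 16S metabarcoding —
measures *relative* abundances: library preparation and fixed sequencing
depth destroy information about the total amount of material per sample.
Differential abundance (DA) analysis nevertheless aims at statements about
*absolute* change. When many features genuinely change in one direction,
the total shifts, and stable features appear to change in the relative
data: a compositional effect that produces false positives. Practical
pipelines counter this with per-sample rescaling (size factors). This
package quantifies, by simulation, how well DA calls made on renormalized
relative counts recover DA calls made on the underlying absolute counts.

`daccord` contains:

* a generative model producing paired absolute (`Y`) and observed (`Z`)
  count matrices with known differential features;
* five from-scratch size-factor strategies — total-count, trimmed mean of
  M-values (TMM), median-of-ratios, pooling-deconvolution, and a
  sampling-fraction bias correction — plus a CLR Dirichlet Monte-Carlo
  test, re-implemented from their algorithmic definitions;
* a shared negative binomial (NB) GLM testing engine, which doubles as
  the absolute-data "oracle";
* scoring (sensitivity/specificity against the oracle), signature
  features of the observed data, and random-forest meta-models that
  predict per-method accuracy from those signatures.

## The generative model

For `P` features, baseline log mean abundances are drawn as
$\theta^{(1)}_p \sim N(m, S^2)$. A feature-correlation matrix
$\Omega$ is drawn from an inverse-Wishart distribution (scale matrix
either the identity or block-exchangeable with a positively correlated
block) and rescaled to unit diagonal. The second condition's log means
are one draw $\theta^{(2)} \sim \mathrm{MVN}(\theta^{(1)}, a\,\Omega)$:
`a` scales the variance of correlated log perturbations, so the typical
per-feature log fold change among perturbed features is
$\sqrt{a}$ on the natural-log scale. Each feature is flagged
differential independently with probability `c`; only flagged features
keep the perturbed mean $\mu^{(2)}_p = e^{\theta^{(2)}_p}$, all others
revert to $\mu^{(1)}_p = e^{\theta^{(1)}_p}$.

Replicate counts (10 per condition by default) are drawn
$y_{ip} \sim \mathrm{NB}(\mu_p \delta_i, 1000)$ with per-sample scale
noise $\delta_i = \max(0.1, N(1, g))$; the size parameter 1000 makes
absolute counts barely overdispersed relative to Poisson
($\mathrm{Var} = \mu + \mu^2/1000$). Finally one common observed depth
$u \sim \mathrm{Unif}(5000, 2\times 10^6)$ (integer-rounded) is drawn
per data set and every sample is multinomially resampled to exactly `u`
counts. This fixed-depth resampling is the crux: column sums of `Z`
carry no information, so all absolute-scale signal must be recovered —
if at all — from composition.

Design choices where the generative description is open:

* **Common depth.** All samples of a data set share one depth `u`. A
  per-sample permutation of original totals would leave residual total
  information; the single common depth implements the stated purpose of
  removing it.
* **`g` is a standard deviation** (like `S`), so the three replicate
  noise levels are directly interpretable as coefficients of variation
  of within-condition totals.
* **`delta` is drawn per sample**, scaling all features in that sample
  jointly — replicate noise in total material, not per-feature noise.
* **Inverse-Wishart concentration.** The default degrees of freedom
  `2P + 50` keep sampling noise on realized correlations small
  (roughly $1/\sqrt{P}$) so the five scale-matrix presets — identity up
  to 50% of features at off-diagonal 0.9 — remain recognizable in the
  drawn matrices.
* **Seeding is hierarchical**: every data set, and every stochastic
  stage within it, derives its own stream from a root seed, so any grid
  cell can be reproduced in isolation.

## Testing engines

**NB GLM.** For each feature, counts follow an NB log-link model with a
two-level condition factor and per-sample offsets (size factors). Group
means and the per-feature dispersion are estimated by alternating
Newton steps (method-of-moments initialization; dispersion floored at
1e-8, profile likelihood maximized on the log scale), and the condition
coefficient is tested with a Wald statistic using observed Fisher
information. The implementation is vectorized across features. In
tests it agrees with per-feature `MASS::glm.nb` fits to ~1e-4 in the
log2 fold change and ~1e-3 in log10 p. Features that are all zero get
p = 1; a group with zero total is handled by a 0.5 pseudo-count on the
fitted mean and flagged. Run on absolute counts with unit offsets this
engine is the *oracle*: its calls define "true" DA for scoring. No
offset is used for the oracle because absolute totals are meaningful
signal there.

The published tools the strategies are modeled on differ in their test
internals (dispersion shrinkage, exact tests, outlier handling). Here
one shared engine is used with pluggable size factors: the strategies
under study differ *only* in how they rescale, which isolates
normalization as the operative difference. Agreement with the original
packages is therefore approximate by construction.

**CLR Dirichlet Monte-Carlo.** For each of 128 instances, per-sample
proportions are drawn from Dirichlet(counts + 0.5), transformed with
the centered log-ratio, and tested per feature with Welch's t; BH
adjustment is applied within each instance and adjusted values averaged
across instances (the fold change is the median across instances of the
between-group CLR difference, rescaled to log2). The CLR removes depth
exactly; the Dirichlet posterior's precision still tracks the counts,
so the Monte-Carlo test is stable — not bitwise invariant — under
per-sample depth rescaling.

**Calling policies.** A feature is called when its BH-adjusted value is
at most `fdr` and its |log2 fold change| at least `lfc_threshold`. The
lenient policy is (0.05, 0); the stringent mitigation policy is
(0.01, 1), i.e. at least two-fold, and is applied to the oracle and the
observed-data calls alike so that both sides of the comparison answer
the same question.

## Size-factor strategies

All strategies return positive factors normalized to geometric mean 1
(any global constant cancels in two-group testing).

* **Total count**: factors proportional to column sums — the
  anticipated worst case. On fixed-depth data all totals are equal, so
  this is equivalent to no correction.
* **TMM**: doubly trimmed (30% on M-values, 5% on A-values),
  inverse-asymptotic-variance-weighted mean of per-feature log2 ratios
  of proportions against a reference sample (the sample whose
  upper-quartile CPM is closest to the mean). The factor describes
  compositional correction only; the GLM uses effective library sizes
  (column total x factor). A 0.5 pseudo-count guards logs of zero;
  with fewer than 3 shared positive features the sample falls back to
  its total-count factor with a warning.
* **Median-of-ratios**: per-feature geometric-mean reference over
  features positive in every sample; factor = median ratio to the
  reference. An optional `controls` argument restricts the reference to
  user-supplied stable features — the control-feature mitigation.
* **Pooling-deconvolution**: samples ordered on a ring by library size;
  pooled counts over sliding windows of several pool sizes are compared
  with an average reference profile; the per-pool median ratios form a
  linear system in the per-sample factors solved by least squares
  (low-weight per-sample equations pin the scale; non-positive
  solutions are floored). With a condition argument, deconvolution runs
  within condition and the blocks are rescaled by the median ratio of
  their pooled profiles. Pool sizes shrink adaptively below the
  published defaults when there are few samples.
* **Sampling-fraction bias correction**: per-sample log offsets
  estimated by alternating trimmed means (20% total trim) on
  log(counts + 0.5); the cross-condition component is identified as the
  trimmed center of per-feature between-condition differences. This is
  a deliberate simplification of the full EM treatment of sampling
  fractions: per-condition feature means plus sample offsets are not
  jointly identified without an assumption, and the trimmed center
  encodes the standard "majority of features stable" assumption.

## The simulation grid

The full grid crosses `P` in {100, 1000, 5000}; five `(m, S)` pairs
(2,1), (3.5,1.5), (5,2), (6.5,2.5), (8,3) on the natural-log scale;
perturbation scale `a` as a proportion of `m` in
{0.05, 0.1, 0.25, 0.5, 1}; five correlation presets; replicate noise
`g` in {0.05, 0.2, 0.5}; and differential proportion `c` in
{0.2, 0.3, 0.5, 0.7, 0.9} — 5625 cells. The numeric levels of `m`,
`S`, `a` and `g` are the package's own choices, made so realized data
spans the intended breadth: percent zeros from near zero (deep, small-P
cells) to above 80% (the P = 5000, shallow-depth corner), within- and
between-condition total fold changes from none to tens-fold, and
detectable differential abundance that is usually a minority of
features even at high `c` (many perturbations are small relative to
counting noise).

Settings are labeled from grid levels: *Microbial* (P <= 1000, highest
`a` level), *Cell Transcriptomic* (P >= 1000, middle `a` levels),
*Bulk Transcriptomic* (P = 5000, lowest two `a` levels); labels may
overlap and cells matching none are "other".

The **reduced grid** — the desk-scale surface used by the acceptance
script and the heavier tests — samples 400 cells uniformly from the
P <= 1000 portion with a seeded RNG. Feature number plays little role
in the benchmark's headline quantities, which makes this an acceptable
cost/fidelity trade: a P = 1000 cell runs in roughly a second, while
the inverse-Wishart draw alone makes a P = 5000 cell two orders of
magnitude slower. Two consequences are documented rather than hidden:
the Bulk setting does not occur on the reduced grid, and the realized
sparsity there tops out near 45% zeros rather than 80%+.

## Scoring, signatures, meta-models

Observed-data calls are scored against oracle calls feature by feature
(TP = both call, FP = observed only, ...). Sensitivity TP/(TP+FN) or
specificity TN/(TN+FP) is recorded as missing when its denominator is
zero and excluded from medians. Aggregation reports per-group medians
plus the percentage of data sets below 95% and below 50% specificity.

`compute_signatures()` produces 48 per-data-set features of the
observed counts (the registry, with one-line definitions, is in
`signature_registry()`): sparsity (zero/one-count proportions, dropout
change), per-condition abundance quantiles, evenness and Gini,
moments and skewness of sampled pairwise CLR feature correlations
(seeded subsample of up to 500 features for cost control), and the
prevalence and spread of apparent per-feature log2 change — including
`prop_large_decrease`/`prop_large_increase`, the fraction of features
at least 1 log2 unit below/above the mean change ("large" is a
configurable package choice; one unit = two-fold). `total_fc` is
identically 1 on fixed-depth simulated data and is retained for user
data.

`train_predictor()` fits a random forest (500 trees, default feature
subsampling) per method and target on an 80/20 seeded unstratified
split, reporting held-out R^2 = 1 - SSE/SST, gain (node-impurity)
importance normalized to sum 1, and per-tree quantile predictive
intervals (25/75 and 5/95 percentiles, clipped to [0, 1]) — the
interval construction is a package choice.

## What passing tests do and do not show

The generator emulates log-normal baselines, correlated log-scale
perturbations, mildly overdispersed counts, within-condition scale
noise and depth-destroying resampling. It deliberately omits
sequencing error, PCR and GC bias, batch effects, UMIs, and
zero-inflation beyond what multinomial undersampling produces.
Accuracy statements made by this package are therefore statements
about compositional distortion and counting noise, not about every
failure mode of real pipelines. Real data sets with strong technical
artefacts can behave worse than any simulated cell; conclusions about
the *ranking* of rescaling strategies transfer more readily than
absolute sensitivity/specificity values.

## Numerical choices and degenerate inputs

* Dispersion floored at 1e-8 (size capped at 1e8); Newton steps on
  means clamped to +/- 3 log units per iteration and on log-size to
  +/- 2 per iteration; four outer alternations.
* All-zero features: p = 1, log2fc = 0, flagged `allzero`. All-zero
  groups: 0.5 pseudo-count on the fitted mean, flagged `pseudo`.
* All-zero samples cannot be resampled (error); the simulator
  substitutes a uniform composition in the pathological case where a
  sample draws no material at all.
* The low-abundance filter keeps features with mean >= 1 in both
  tables; the boundary is inclusive.
* Ties in trimmed means and medians follow R's default conventions;
  quantile trimming in TMM uses type-7 quantiles.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the 400-cell reduced grid
(about 7 minutes on one CPU), 128 Dirichlet instances for the CLR test,
and meta-model corpora of 120-300 rows; one P = 100 cell completes in
well under a second, a P = 1000 cell in about one to two seconds.
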