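---
title: "Methods: discriminative microbial signatures in microsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminative microbial signatures in microsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsig)
```

## The problem

Given per-rank relative-abundance tables (samples x taxa, percent scale)
from a two-group case-control cohort — the motivating application is a
pancreatic-cancer cohort of 25 non-metastatic and 28 metastatic patients —
the package asks two complementary questions:

1. Which *groups* of taxa, acting together through their average
   standardized abundance, separate the two classes? (supervised
   clustering: `pelora()`)
2. Which individual taxa and which taxon-taxon *interactions* drive a
   nonparametric classifier of the class label, and how does predicted
   risk move with abundance? (`irf()`, `mine_interactions()`,
   `ale_curve()`, `pdp_surface()`)

The two branches are deliberately independent: they consume the same
transformed matrix and never feed each other. A third, smaller component
maps discriminating taxa onto metabolite intensities through Spearman
rank correlations (`spearman_matrix()`).

## The abundance transform

Relative abundances `q` (percent, 0-100) are carried through three steps:

* **Zero replacement.** `0%` has no logit; every exact zero becomes half
  of the smallest nonzero percent observed in the entire matrix
  (`replace_zeros()`). This is the half-minimum convention for values
  below the detection limit.
* **Logit.** `x = log(p / (1 - p))` with `p = q / 100`, mapping percents
  to the whole real line.
* **Z-score.** Each taxon column is standardized to mean 0, sample SD 1
  (denominator `n - 1`) over the *pooled* cohort, never per group. A
  taxon observed at 0% everywhere is constant after replacement; it is
  set aside with its constant recorded rather than standardized
  (`logit_zscore()`).

Pooled standardization has a useful arithmetic consequence: group means
of a Z-scored taxon satisfy `n0 m0 + n1 m1 = 0`. For a taxon absent from
one group, the within-group constant is therefore determined by the other
group's mean (`impute_absent_z()`), which is how `centroid_group_means()`
reconstructs published cluster centroids from per-member group means —
including for members tabulated as "Absent" in one group.

The choice of the `n - 1` SD is a convention; nothing downstream depends
on it beyond a constant factor. Welch's unequal-variance t-test is the
default two-group comparison, switching to the Mann-Whitney U test when
either group has zero variance (`compare_groups()`), where the t
denominator degenerates.

## PELORA: supervised clustering

A cluster `C` is summarized by its centroid, the per-sample unweighted
mean of member Z-scores. Centroids enter a logistic model whose fit is
judged by the L2-penalized negative log-likelihood

```
J(beta) = -sum_i [ y_i log pi_i + (1 - y_i) log(1 - pi_i) ] + lambda * sum_j beta_j^2
```

with `pi = plogis(X beta)`, the intercept unpenalized (standard ridge
convention), and the inner fit done by damped Newton/IRLS iterations to a
gradient norm below 1e-8 (`fit_ridge_logistic()`). Growth is greedy: at
each step every unused taxon is tried (recompute centroid, refit all
coefficients) and the taxon with the largest criterion decrease is kept;
growth stops when no candidate improves the criterion by more than
`tol = 1e-6`. A finished cluster's membership is frozen but its centroid
stays in the design, so cluster 2 grows *conditionally* on cluster 1. At
most two clusters are returned by default — an interpretability cap, not
an algorithmic one. Members enter centroids with coefficient +1 (plain
mean); a sign-flip mode exists but is off by default because published
centroids of this analysis are plain means over members whose shifts may
point in either direction.

The penalty is chosen by `tune_penalty()`: bootstrap resamples of the
cohort, out-of-bag 0/1 misclassification at threshold 0.5, the penalty
with the lowest median rate wins, and ties resolve toward the *largest*
penalty (more regularization, stabler clusters). The default grid is 13
log-spaced values from 1e-3 to 1e3 with 50 resamples; neither the grid
nor the resample count is prescribed by the source analysis, so both are
package defaults.

Numerical notes: fitted probabilities are clipped at 1e-12 before logs;
bootstrap resamples that lose a class are redrawn; with `lambda = 0` on
separable data the unpenalized fit diverges, so tuning grids start at a
positive penalty.

## Iterative Random Forests and interaction mining

`irf()` fits `K` successive random forests (via \pkg{ranger}). Iteration
1 samples split candidates uniformly; iteration `k + 1` samples them with
probability proportional to iteration `k`'s Gini importances (negatives
clipped to zero, renormalized; if fewer than `mtry` stay positive, a 0.1%
uniform admixture keeps node sampling feasible). Out-of-bag class-1
probabilities are unweighted vote fractions over the trees not containing
each sample; discrimination is summarized by the rank-form ROC AUC with a
95% CI from 1000 stratified (within-class) bootstrap replicates
(`roc_auc()`). Importances are reported rescaled so the maximum is 100%
(`relative_vimp()`). `tune_iterations()` picks `K` from a grid confined
to 1..100 by OOB AUC, smallest `K` on ties.

Interactions are mined by generalized Random Intersection Trees
(`mine_interactions()`): on each of `n_boot` outer bootstrap resamples
the `K`-iteration forest is refit; every leaf predicting class 1
contributes the set of distinct features on its root-to-leaf path,
weighted by its training-sample count; random intersection trees
(depth 5, branching 2 by default) repeatedly intersect sampled itemsets,
and the surviving sets of order >= 2 are that bootstrap's candidates. An
interaction's **stability score** is the fraction of bootstraps that
recover it. Path-itemset semantics (rather than signed/thresholded binary
features) are a documented design choice; the source text does not pin
down the mapping.

One addition to the textbook RIT output proved necessary for calibration:
a candidate only counts as recovered within a bootstrap if at least a
small fraction (default 4%) of the intersection trees emit it. Prevalent
itemsets survive many trees; chance intersections survive isolated ones.
Without this support filter, forests refit on overlapping bootstrap
resamples of *label-permuted* data repeatedly rediscover the same
spurious pairs, inflating null stabilities toward 0.5; with it, planted
pairs (path-containment frequency ~0.5-0.7) remain near-certain
recoveries while null pairs (<= ~0.36) drop out.

Defaults follow the published iRF reference settings: 500 trees,
`mtry = ceiling(sqrt(p))`, depth-5 branch-2 RIT with 500 trees, 30 outer
bootstraps. The original study's exact tuning grid lives in supplemental
material that is not reproduced here; these defaults are the package's
own.

## Interpretation: ALE and PDP

`ale_curve()` computes first-order Accumulated Local Effects on quantile
bins (20 by default; bins emptied by ties — e.g. mass at the replaced-zero
value — are merged). The local effect of a bin is the mean prediction
difference when only the target feature is moved between the bin edges;
effects are accumulated and centered so the count-weighted mean is zero,
making `ALE = 0` the cohort-average predicted risk and `ALE = 0.30` a
risk 30 points above it. `pdp_surface()` clamps a feature pair to a
20 x 20 marginal-quantile grid and averages predictions over all samples;
cells at or above 0.5 are flagged high-risk. Display thresholds are pure
filters and mirror the published figures: ALE for features with relative
VIMP > 10%, PDP for pairs with stability > 0.70, network edges at
stability >= 0.5. Features are interpreted on the logit scale — forests
are invariant to that monotone transform, and the axes then match the
transform used everywhere else.

## Associations

`spearman_matrix()` correlates taxa against metabolite columns with
Spearman's rho (Pearson on average ranks) and two-sided p-values from the
`t` approximation on `n - 2` degrees of freedom. The significance mask is
raw `p < 0.05` by default, matching the source convention of reporting
unadjusted associations; a Benjamini-Hochberg option is provided for
users who want error control. Because rho is rank-based, running the
analysis on raw percents, logit percents or Z-scores gives identical
results.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical shape of the motivating
cohort: 53 samples (25/28) by default, per-rank taxon counts of roughly
20 phyla / 60 families / 150 genera / 300 species, heavy right skew, and
a 30% detection-limit zero rate. Per taxon `t` and sample `i`,

```
L[i, t] = mu_t + delta * 1[group_i = 1, t planted] + sd_t * eps_it
```

with `mu_t ~ N(-4, 2.5^2)` and a base scale `U(0.5, 1.5)` damped by
`clamp(-mu_t / 4, 0.3, 1)` — abundant core taxa fluctuate less than rare
ones, a standard observation in gut-microbiome time series, and the
damping also keeps the softmax denominator from being dominated by a few
volatile taxa. Percent compositions are the closure
`100 * exp(L) / rowsum(exp(L))` (rows sum to 100 exactly); entries below
the `zero_rate` quantile of all percents are then set to 0%.

Planted structure is placed on an *exchangeable module*: member taxa get
`mu = -3` exactly and unit base scale. Three design points deserve
explanation because the first drafts of the generator did them
differently and the benchmarks exposed why that was wrong:

* **Homogeneous member scale.** If members' latent scales vary, a fixed
  logit shift `delta` translates into wildly different standardized
  effects, and the criterion-optimal cluster is a strict subset of the
  planted one — the benchmark then punishes correct behaviour.
* **Moderately rare placement.** Members near `mu = -2` carry enough
  compositional mass that shifting them moves every other taxon's logit
  through the closure denominator, eating 0.3-0.5 of the planted shift
  and creating mirror-image pseudo-signal on all noise taxa; members far
  below the detection limit are unobservable. `mu = -3` avoids both.
* **Labels from observed features.** When a pairwise interaction is
  planted, class labels are drawn from a logistic rule
  (`beta0 + b1 s1 + b2 s2 + b12 s1 s2`, defaults 0, 1.5, 1.5, 4.5) on the
  *observed* standardized logit abundances — after closure, zeroing and
  replacement — not on the raw latents. Ground truth must live on what a
  classifier can see, or recovery failures conflate method error with
  unidentifiability.

Metabolite columns are Gaussian latents mapped to positive intensities;
a planted association with target Spearman `rho` uses the Gaussian-copula
loading `2 sin(pi rho / 6)` on the observed logit abundance of the anchor
taxon.

What the generator does **not** emulate: phylogenetic correlation between
taxa, sequencing-depth variation and count noise, batch effects, and the
long-tailed library-size artefacts of real 16S data. Passing recovery
benchmarks on these cohorts therefore demonstrates algorithmic
correctness under the stated model, not field performance on raw
sequencing runs.

## Benchmark problem sizes

The recovery and calibration suites use fixed, documented sizes chosen to
make each property measurable on a single CPU: supervised-clustering
recovery uses 20 cohorts of n = 60 with 45 taxa, a 5-taxon module and
`delta = 1.5` (penalty fixed at 0.1 for determinism; the full analysis
would tune it); interaction mining uses 20 cohorts of n = 200 with 20
taxa, forests of 200 trees, `K = 3`, `mtry = 3`, 20 bootstraps and 200
intersection trees, with a label-permutation null run under identical
settings; oracle-equivalence checks run exhaustive forward search on 20
random instances with up to 8 features. Published-value checks (centroid
arithmetic, the hand-computable AUC case) are exact to the printed
precision.

## Known limitations

* Greedy growth with coefficient refitting is a heuristic; it matches
  exhaustive forward search step-by-step (verified), but neither is a
  global optimizer over clusterings.
* Stability scores are bootstrap frequencies, not p-values; the
  permutation null in the test suite is the calibration reference.
* OOB AUC at n ~ 53 has wide confidence intervals; the stratified
  bootstrap quantifies but cannot shrink that uncertainty.
* Chao1 requires integer counts; on relative abundances it is reported
  missing rather than approximated.
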