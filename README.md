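# microsig

Discriminative microbial signatures from case-control relative-abundance
profiles.

Gut-microbiome case-control studies — the motivating application is a
cohort of pancreatic-cancer patients with (n = 28) and without (n = 25)
metastases — ask which bacteria, alone or together, separate the two
patient groups. `microsig` implements the two-branch analysis used for
that question:

1. **PELORA supervised clustering.** Relative abundances are
   logit-transformed (zeros replaced by half the dataset minimum) and
   Z-scored over the pooled cohort. Clusters of taxa are grown greedily
   so that their *centroids* (per-sample mean member Z-score) minimize an
   L2-penalized negative Bernoulli log-likelihood

   `J(beta) = -sum_i [y_i log pi_i + (1-y_i) log(1-pi_i)] + lambda sum_j beta_j^2`

   with the penalty tuned by bootstrap out-of-bag misclassification. At
   most two clusters are kept for interpretability.

2. **Iterative Random Forests (iRF) with interaction mining.** Forests
   are refit K times with split-candidate sampling weighted by the
   previous iteration's Gini importances; class-1 decision paths are
   converted to itemsets and mined with generalized Random Intersection
   Trees across outer bootstraps. Each recovered taxon-taxon interaction
   carries a *stability score* (fraction of bootstraps recovering it;
   0 = unstable, 1 = stable). The forest is summarized by out-of-bag ROC
   AUC with a 1000-replicate stratified-bootstrap 95% CI, relative
   variable importance (% of maximum), Accumulated Local Effects curves
   and two-feature partial-dependence surfaces.

A Spearman association module links discriminating taxa to metabolite
intensities, and a synthetic-cohort generator with planted ground truth
(cluster shifts, pairwise label interactions, taxon-metabolite
correlations) supports recovery benchmarking of the whole pipeline. The
two analysis branches are independent by construction: disabling one
leaves the other's outputs byte-identical.

## Worked example

```r
library(microsig)

spec <- simulation_spec(n_per_group = c(25, 28), n_taxa = c(genus = 60),
                        planted_cluster = list(rank = "genus",
                                               taxa = 1:5, delta = 1.5),
                        seed = 42)
cohort <- simulate_cohort(spec)
z <- transform_abundance(cohort$tables$genus)
z
#> zscore_matrix: 53 samples x 54 features (genus rank), 6 constant feature(s) dropped

fit <- pelora(z, lambda = 0.1)
fit
#> PELORA fit: 2 cluster(s), lambda = 0.1, criterion = 4.8492
#>   cluster 1 (5 taxa): genus_002, genus_001, genus_005, genus_003, genus_004
#>   cluster 2 (7 taxa): genus_048, genus_044, genus_040, genus_035, genus_020, genus_009, genus_043

summary(fit)$clusters[[1]]$centroid
#> centroid of 5 taxa: group means -0.740 vs 0.661 (t, p = 4.97e-19)

score_recovery(fit$clusters[[1]], cohort$truth$cluster)
#> $overlap
#> [1] 1
#> $jaccard
#> [1] 1

rf <- irf(z, K = 3, n_trees = 300, seed = 42)
rf
#> iRF fit: K = 3 iterations, 300 trees, mtry = 8
#>   OOB AUC = 0.996 (95% CI 0.983-1.000)
#>   top VIMP (%): genus_005=100.0, genus_003=66.9, genus_004=48.7, genus_001=46.8, genus_002=27.9
```

The planted 5-taxon module is recovered exactly as cluster 1: its
centroid separates the groups by 1.4 Z-units (−0.740 vs 0.661), and the
same five taxa top the iRF importance ranking. Cluster 2 collects a
weaker secondary pattern, as the two-cluster analysis is designed to do.

`run_pipeline()` drives everything (transform → PELORA and
transform → iRF → ALE/PDP, plus associations) from one YAML config and
one root seed, writing TSV/JSON outputs and a manifest with checksums;
`inst/scripts/run_pipeline.R` is a shell wrapper around it.

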