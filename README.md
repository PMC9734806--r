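# pancut

Assisted clustering of gene-expression profiles using regulatory omics
(e.g. DNA methylation beta values) measured on a **different but partially
overlapping** set of individuals.

Co-expression clustering is usually driven by observed expression alone,
which mixes regulated signal with noise.  When an upstream regulatory data
type is available for some individuals — even if only a fraction of them
also have expression data — the regulated component of expression can be
predicted and used to sharpen the clustering.  `pancut` is aimed at
statistical geneticists and computational biologists integrating bulk
expression with methylation or genotype cohorts that only partly share
samples.

## The method

Individuals split into three blocks: `n1` with expression only, `n2` with
both (the overlap), `n3` with regulators only.

1. **Regulation.**  For each gene *j*, an elastic net on the overlap:

   βĵ = argmin ‖Yⱼᴼ − β₀ − Xᴼβ‖² + λⱼ[(1 − αⱼ)‖β‖² + αⱼ‖β‖₁],

   with (λⱼ, αⱼ) tuned by 5-fold CV.  Predicted (regulated) expression
   Ŷ = Xβ̂ is computed for all n2 + n3 regulator-bearing individuals.

2. **Similarity.**  Gene–gene similarities are inverse Euclidean
   distances: **S** from observed expression, **Ŝ** from predicted
   expression (on standardized gene profiles; see the methods vignette).

3. **Clustering.**  A partition A₁, …, A_K minimises

   Σₖ cut(Aₖ, Aₖᶜ; S) / cutvol(Aₖ; Ŝ),

   i.e. between-cluster similarity on the observed data over
   within-cluster similarity on the regulated component, by simulated
   annealing over single-gene moves (10,000 iterations by default).

4. **Choosing K.**  Average-silhouette or elbow (max discrete second
   difference of WCSS) on distances 1/ŝⱼₗ derived from Ŝ.

Comparator modes: complete-data assisted clustering (`mode = "full"`),
overlap-only (`mode = "subset"`), and a K-means baseline on observed
expression.  Accuracy against a reference partition is the ±1
adjacency-matrix agreement Σ(C_T ⊙ Ĉ)/p².  Two synthetic benchmark
scenarios (block-structured regulators; sparse regulator-to-gene
transition matrix; structured error covariance; configurable overlap
fraction `pcnt` and expression share `f`) make the whole pipeline testable
without any cohort data.

## Worked example

```r
library(pancut)

cfg <- sim_config("I", n = 400, p = 150, q = 90, K = 3,
                  pcnt = 1/2, f = 0.5, seed = 42)
d <- simulate_dataset(cfg)

reg <- fit_all_genes(d, seed = 1)
glance(reg)
#> # A tibble: 1 × 5
#>   n_genes n_regulators n_regulated n_overlap cv_folds
#> 1     150           90         148       200        5

imputation_quality(reg, d, mode = "holdout", seed = 2)
#> <imputation_quality> holdout(0.35): median R^2 = 0.2019 (range 0 to 0.88)

fit <- assisted_cluster(d, K = 3, regulation = reg, sa = sa_config(seed = 3))
fit
#> <ancut_fit> 150 genes in 3 clusters; objective = 5.7571
#>   sizes: 53, 48, 49
#>   accepted moves: 224 / 10000

clustering_accuracy(d$true_partition, fit)
#> <accuracy_report> M_accuracy = 0.5486 (p = 150, K_true = 3, K_est = 3)

km <- kmeans_baseline(d$y, 3, seed = 4)
clustering_accuracy(d$true_partition, km)
#> <accuracy_report> M_accuracy = 0.0576 (p = 150, K_true = 3, K_est = 3)
```

With half the individuals lacking one of the two data types, the assisted
partition recovers most of the planted structure (M = 0.55) where K-means
on observed expression alone stays near the random-partition floor for
K = 3 (≈ 0.11).  The median holdout R² of 0.20 shows that even modest
imputation quality is enough to assist the clustering.

Fitted objects have `tidy()` / `glance()` methods and `autoplot()`
(annealing trace, K-selection curve, R² histogram, batch accuracy).
Replicated benchmarks run through `run_simulation_batch()`.  A thin
command-line interface over the same functions lives at
`inst/cli/pancut.R` (subcommands `simulate`, `fit`, `cluster`, `select-k`,
`evaluate`, `bench`).

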