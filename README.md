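# grassmerge

Multi-omics patient subtyping by Grassmann subspace merging, with the
downstream characterization stages that typically follow it: moderated-t
differential expression, hypergeometric over-representation analysis, and a
phecode-based PheWAS over eQTL genotypes. The package is aimed at analysts
who have matched per-patient omics matrices (e.g. brain expression,
proteomics, DNA methylation) and want a tested, reproducible implementation
of the whole subtype-discovery workflow — including a synthetic-data
generator with planted ground truth, so every stage can be validated
without access to controlled-access cohort data.

## The method

Each modality's patients-by-features matrix (aligned, kNN-imputed,
top-75 %-variance filtered, standardized) becomes a similarity graph with a
density-adaptive heat kernel,

    S_ij = exp(-||x_i - x_j||^2 / (sigma_i sigma_j)),   S_ii = 0,

where `sigma_i` is the distance to the 7th nearest neighbour. Its symmetric
normalized Laplacian `L = I - D^{-1/2} S D^{-1/2}` is embedded by the k
eigenvectors of smallest eigenvalue, giving an orthonormal `U^(m)` — one
point on the Grassmann manifold G(k, N) per modality. The consensus
subspace minimizes

    sum_m tr(U' L^(m) U) + alpha * sum_m d2proj(U, U^(m)),
    d2proj(U, V) = k - tr(U U' V V'),

solved in closed form as the bottom-k eigenvectors of
`L_mod = sum_m L^(m) - alpha * sum_m U^(m) U^(m)'`. Patients are clustered
by seeded K-means (10 restarts) on the row-normalized consensus embedding,
and the number of clusters is selected by mean silhouette over k = 2..8.
Cluster contrasts are then tested per feature with empirical-Bayes
moderated t-statistics (BH FDR < 0.05 and |logFC| >= 0.7), gene lists with
the one-sided hypergeometric test (qscore = -log10 adjusted p), and eQTLs
of the differential genes against EHR-derived phecodes with
covariate-adjusted logistic regression and dual (global and per-eQTL) BH
correction.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated 80-patient,
three-modality cohort with two planted subtypes (`Rscript
analysis/01_simulate_cohort.R` through `05_phewas.R`). Condensed:

```r
library(grassmerge)

mods <- lapply(c("rna", "prot", "meth"), function(nm)
  list(name = nm, n_features = 200, n_informative = 60,
       effect_size = 4, noise_sd = 1))
sim  <- simulate_multiomics(80, 2, mods, seed = 20260901)
prep <- preprocess_modalities(sim$matrices)
cr   <- select_k(prep, alpha = 0.5, k_range = 2:8, seed = 20260901)
cr$k_selected
#> [1] 2
round(cr$silhouette_by_k, 3)
#>     2     3     4     5     6     7     8
#> 0.983 0.558 0.354 0.328 0.267 0.211 0.195
table(cr$labels, sim$labels)   # perfect recovery up to label swap
#>      1  2
#>   1  0 40
#>   2 40  0

de <- run_diffexpr(prep$rna, factor(cr$labels), fdr = 0.05, lfc = 0.7)
sum(de$significant)
#> [1] 60
```

The silhouette trace peaks sharply at the planted k = 2; the 60
significant features are exactly the informative block that survived the
variance filter. `analysis/04_enrichment.R` then ranks the planted
annotation term first (qscore 16.8), and `analysis/05_phewas.R` recovers
the planted eQTL effect (true per-allele OR 1.8, estimated 1.74,
per-eQTL-adjusted p ≈ 1e-11) while leaving the null variant at p > 0.05.

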