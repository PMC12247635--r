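---
title: "Patient subtyping by Grassmann subspace merging: model and methods"
author: "grassmerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient subtyping by Grassmann subspace merging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassmerge)
```

## The problem

Molecular subtyping asks whether a patient cohort splits into groups that
share coordinated molecular state across several omics layers — for example
brain gene expression, proteomics and DNA methylation in a dementia cohort.
No single modality is trusted to define the partition: each is noisy, each
measures a different layer, and feature scales are incomparable across
layers. `grassmerge` implements an intermediate-integration strategy: each
modality is first converted to a patient-to-patient similarity graph, each
graph to a low-dimensional spectral subspace, and the subspaces are then
merged geometrically before a single clustering is performed. Downstream
stages characterize the discovered subtypes: moderated-t differential
expression, hypergeometric over-representation of the resulting gene lists,
and a phecode-based PheWAS over eQTLs of the differential genes.

## Per-modality preprocessing

Each modality arrives as an $N \times p_m$ patients-by-features matrix on
its native (already log-scale or beta-value) units. The chain is fixed:

1. **Sample alignment** — all matrices are restricted to the intersection of
   sample IDs, in the order the shared IDs appear in the first matrix. Every
   later stage assumes row $i$ is the same patient everywhere.
2. **kNN imputation** (`knn_impute`, default $k = 100$) — each missing entry
   is the mean of that sample's values over the $k$ nearest *features*
   (probe-neighbour convention, the standard choice for methylation arrays).
   Feature distance is Euclidean over commonly observed samples with the
   usual pairwise-complete rescaling. Neighbours-as-features rather than
   neighbours-as-samples is a convention choice: with many more probes than
   patients, probe neighbourhoods are estimated far more stably.
3. **Variance filtering** (`variance_filter`, keep 0.75) — the top 75 % of
   features *ranked by variance* are retained. We read "top 75 % of
   variance" as a per-feature rank cut, not as "features accounting for
   75 % of total variance"; the rank cut is the common practice and the
   other reading would retain very few features in heavy-tailed variance
   distributions. Ties break by input order, so the result is deterministic
   and invariant to sample reordering.
4. **Standardization** (`standardize`) — each retained feature is centred
   and scaled to unit variance with divisor $n - 1$. The divisor is a
   convention; any consistent choice rescales all features uniformly and
   leaves the similarity graph's geometry unchanged up to the kernel
   bandwidth. Zero-variance features are dropped with a warning.

Filtering runs on complete (imputed) data, and standardization runs last so
the graph kernel sees unit-scale features.

## The integration core

**Similarity graph.** For modality $m$ with standardized rows $x_i$,

$$S^{(m)}_{ij} = \exp\!\left(-\frac{\lVert x_i - x_j \rVert^2}{\sigma_i
\sigma_j}\right), \qquad S_{ii} = 0,$$

where $\sigma_i$ is the Euclidean distance from $x_i$ to its 7th nearest
neighbour (capped at $N-1$). The per-point bandwidth adapts to local
density, so tight and loose regions of the patient cloud contribute
comparable edge weights. Duplicate profiles would give $\sigma_i = 0$; the
bandwidth then falls back to the smallest positive neighbour distance, and
a cohort of entirely identical patients is rejected.

**Laplacian and spectral subspace.** Each graph yields the symmetric
normalized Laplacian $L^{(m)} = I - D^{-1/2} S^{(m)} D^{-1/2}$, whose
eigenvalues lie in $[0, 2]$. The $k$ eigenvectors with *smallest*
eigenvalues form $U^{(m)} \in \mathbb{R}^{N \times k}$, an
orthonormal-column matrix treated as a point on the Grassmann manifold
$\mathcal{G}(k, N)$.

**Merging.** Subspace dissimilarity is the squared projection-Frobenius
distance $d^2_{proj}(U, V) = k - \mathrm{tr}(U U^\top V V^\top)$, the sum
of squared sines of the principal angles. The consensus solves

$$\min_{U^\top U = I} \; \sum_m \mathrm{tr}(U^\top L^{(m)} U) +
\alpha \sum_m d^2_{proj}(U, U^{(m)}),$$

whose minimizer spans the bottom-$k$ eigenvectors of the modified Laplacian
$L_{mod} = \sum_m L^{(m)} - \alpha \sum_m U^{(m)} U^{(m)\top}$. All
modalities enter with equal weight. Two conventions deserve note:

* **Which end of the spectrum.** "Top $k$ eigenvectors of $L_{mod}$" is
  taken to mean the eigenvectors of the $k$ smallest eigenvalues. This is
  the only reading consistent with Laplacian spectral clustering — the
  first term of the objective is minimized by small-eigenvalue directions,
  and subtracting $\alpha \sum U^{(m)} U^{(m)\top}$ *lowers* the eigenvalues
  of directions the modality subspaces agree on, pulling them into the
  retained bottom block.
* **The trade-off weight $\alpha$.** Nothing pins a value; the default is
  0.5, a midpoint between pure structure preservation ($\alpha = 0$, where
  the pipeline reduces exactly to spectral clustering of the summed
  Laplacian) and strong subspace agreement. The recovery properties in the
  test suite are checked at $\alpha \in \{0.1, 0.5, 1\}$; within this range
  the choice does not move the results on well-separated data.

Eigenvector signs are fixed by making each column's largest-magnitude entry
nonnegative — determinism across linear-algebra backends. Within degenerate
eigenvalue blocks the solver's order is kept, and all subspace comparisons
in the tests use the Grassmann distance, which is basis-independent, never
raw eigenvectors.

**Clustering and model selection.** Rows of the consensus $U$ are scaled to
unit norm (the standard spectral-clustering normalization; the alternative
reading, column rescaling, would not change the spanned subspace but row
normalization is what makes K-means on embedding rows meaningful) and
partitioned by K-means: Euclidean, 10 random restarts, 300 iteration cap,
seeded, best within-cluster sum of squares wins, ties to the first
attained. For each candidate $k$ in 2–8 the whole embedding is *recomputed
at dimension $k$* — subspace dimension is tied to the candidate cluster
count, the standard coupling and the only reading that makes the per-$k$
loop well defined — and the mean silhouette width (Euclidean, on the
normalized rows) scores the partition. The $k$ with the highest mean
silhouette is selected and the full trace is reported.

## Differential expression

Between the two discovered clusters, each feature is fit by OLS on a shared
design (intercept, cluster indicator, covariates such as age and sex); the
cluster coefficient on already-log-scale data is the logFC (cluster 1 minus
cluster 2). Variances are moderated by the standard empirical-Bayes
scaled-F model: the mean and spread of the log residual variances are
matched to digamma/trigamma moments to estimate a prior $(d_0, s_0^2)$, and
each posterior variance is $(d_0 s_0^2 + d\,s_g^2)/(d_0 + d)$. When the
observed spread does not exceed chi-square sampling noise the prior df is
infinite and all variances pool to their mean. The moderated $t$ uses
$d_0 + d$ degrees of freedom; $d_0 = 0$ recovers the classical two-sample
$t$-test exactly, which is the module's internal correctness anchor, and
the estimator agrees with the reference empirical-Bayes implementation to
machine precision on shared fixtures (checked in the test suite).
Significance is the conjunctive rule BH-adjusted $p < 0.05$ **and**
$|logFC| \ge 0.7$; a `use_raw_p` switch substitutes the raw $p$ for
low-signal tissues such as blood. Features with zero residual variance and
zero coefficient get $t = 0$, $p = 1$ rather than 0/0.

## Enrichment

Over-representation of a gene list is tested per term by the one-sided
hypergeometric upper tail, evaluated in log space, BH-adjusted across
terms, and summarized as $\mathrm{qscore} = -\log_{10}(p_{adj})$. The
universe is the set of features that survived preprocessing — conditioning
on testable features rather than the whole genome is the defensible ORA
choice when the paper-level universe is unstated. Terms outside 5–2000
genes are not tested (configurable); genes outside the universe are dropped
with a warning.

## PheWAS

The eQTL stage keeps, per differential gene, at most the three eQTLs with
smallest FDR among those below $10^{-4}$ (lexicographic variant-ID
tie-break). Phecode phenotypes follow the phenotyping rules: at least two
distinct event instances (distinct = distinct dates) make a case; exactly
one instance is treated as *missing* by default — the cited phenotyping
convention — with `one_instance = "control"` available for the literal
"FALSE = control" reading; sex-restricted phecodes are masked for the other
sex; phecodes with fewer than 20 cases or 20 controls are dropped. Each
(variant, phecode) pair is fit by logistic regression (IRLS, 50 iterations,
deviance tolerance $10^{-8}$) with additive allele coding — the PheWAS
default, giving per-allele odds ratios — adjusted for age, sex and six
principal components; sex-restricted phecodes omit the sex covariate.
Monomorphic dosage, single-level outcomes, non-convergence and separation
($|\beta| > 15$ on the logit scale, no penalized fallback) are recorded as
missing with a reason code. BH runs twice over the non-missing tests:
globally and within each variant; rows with raw $p < 10^{-4}$ are flagged
for reporting.

## The synthetic cohort generator

All stages are exercised on generated data with planted ground truth,
because the real cohorts behind this kind of analysis are controlled-access.

* `simulate_multiomics` plants one partition shared by every modality. The
  informative features of each modality are split into one block per
  cluster; block-$g$ features have mean `effect_size * noise_sd` in cluster
  $g$ and 0 elsewhere, so cluster centroids are vertices of a regular
  simplex — every pair of clusters is separated by the same standardized
  effect, and for two clusters every informative feature shifts by exactly
  the stated effect. Nuisance features are pure noise. Defaults used
  throughout the tests: 80 patients, 3 modalities, 120 features of which 40
  informative, unit noise — small enough to run in seconds, large enough
  that the 7-NN bandwidth and the variance filter behave as on real data.
* `simulate_geno_pheno` draws dosages in Hardy–Weinberg proportions,
  phenotypes from a logistic model with known per-allele log-odds and
  age/sex/PC covariate effects, and an EHR stream in which cases receive at
  least two distinct-date instances and a designated fraction of non-cases
  exactly one (exercising the one-instance rule). The six PCs are standard
  normals independent of genotype by default, with a `confound_pcs` switch
  that correlates PC1 with dosage to exercise covariate adjustment.
* `simulate_annotation` builds a universe, random terms, and one planted
  term whose overlap with the selected list strictly exceeds its
  hypergeometric expectation; infeasible or unenriched plantings are
  rejected at construction.

What the generator does **not** emulate: linkage disequilibrium, the
bimodal shape of methylation beta values, batch effects, feature-feature
correlation within a modality, and informative missingness. Passing tests
therefore demonstrate that the machinery is correct and calibrated under
clean Gaussian/binomial sampling, not that the pipeline is robust to every
artefact of real cohorts.

## Numerical choices and degenerate inputs

* Heat-kernel bandwidth falls back to the smallest positive neighbour
  distance under duplicated profiles; all-identical input is an error.
* Isolated graph nodes (zero degree) and rank-deficient designs are errors
  naming the offending sample or column.
* The Laplacian and $L_{mod}$ are symmetrized as $(A + A^\top)/2$ after
  assembly to absorb floating-point asymmetry before `eigen(symmetric =
  TRUE)`.
* BH adjustment validates its input range; hypergeometric configuration
  violations are errors rather than silent clamping.
* One seed drives a run; per-stage and per-$k$ streams are derived from it
  deterministically, so a pipeline rerun is bit-identical (the manifest's
  checksums make any silent change visible).

## Known limitations

* **Silhouette selection across re-computed embeddings.** Because the
  embedding is recomputed at every candidate $k$, mean silhouettes at
  different $k$ compare different geometries. With three well-separated
  planted clusters the $k = 2$ merge can score a marginally higher
  silhouette than the near-perfect $k = 3$ partition in a small fraction of
  replicates (photo-finish margins under 0.005). This is a property of the
  prescribed selection procedure itself, visible in the selection-rate
  experiments, not of the merging step.
* Modality weighting is uniform by design; no adaptive fusion.
* The moderated-t module implements the single-design, two-group contrast
  path only — no precision weights, duplicate correlation or array quality
  weights.
* The PheWAS fit has no penalized (Firth) fallback; separated fits are
  reported missing rather than estimated.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
cohorts of 80–81 patients for the integration experiments (10–24 seeds per
condition), 1000-feature DE simulations (5–10 seeds), 500–600 logistic fits
for PheWAS calibration, and 5000-participant power replicates. These sizes
were chosen so the full suite completes in well under a minute on one core
while keeping Monte-Carlo error comfortably inside the asserted margins.
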