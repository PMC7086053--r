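---
title: "Models and methods behind landgf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind landgf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`landgf` chains eight analysis stages, from genotype QC to climate-change
genetic offset. This vignette explains the model behind each stage, the
tunable parameters and their defaults, the numerical choices that were
genuinely open, and what the synthetic benchmark does and does not
demonstrate about real data.

## The synthetic landscape generator

All tests and the acceptance benchmark run on data from
`generate_landscape()` / `simulate_allele_frequencies()` /
`sample_genotypes()`. The generative model is deliberately the *simplest*
process exhibiting the statistical structure the downstream methods assume:

* **Climate surfaces.** Each environmental variable is a linear gradient, a
  sinusoid, or a Gaussian random field with exponential covariance
  `cov(d) = σ² exp(−d/ρ)` over cell coordinates (autocorrelation length ρ
  in degrees). The default variable set mimics the kinds of predictors used
  for temperate conifers (reference evaporation on a west–east gradient,
  winter degree-days on a latitude gradient, seasonal precipitation,
  climatic moisture deficit as autocorrelated noise).
* **Allele frequencies.** Every locus l has a baseline logit
  `a_l = logit(p₀)`, `p₀ ~ U(0.1, 0.9)`, and drifts on its own Gaussian
  random field over the population coordinates (default sd 0.6, range 3°),
  which produces tunable isolation by distance without coalescent
  machinery. Adaptive loci add `β·z_v` on the logit scale, where `z_v` is
  the standardized driver variable — a logistic cline, hence isolation by
  environment. Adaptive loci carry the *same* drift field as neutral ones,
  so at β = 0 the two classes are exchangeable by construction; this is
  asserted by a two-sample KS test in the suite.
* **Genotypes.** Individuals are `Binomial(2, p)` draws; missing calls are
  completely at random (default rate 5%; the field's data give no reason to
  prefer an informative mechanism). SNPs are grouped into GBS-like
  fragments (sizes uniform on 1–5, mean 3) and written to a GT-only
  VCF 4.2 with the fragment id as CHROM, so fragment thinning round-trips
  through the reader. Within-fragment SNPs are *independent* draws: the
  generator deliberately does not model within-fragment linkage
  disequilibrium beyond the shared fragment id, because nothing downstream
  consumes LD — thinning only needs the grouping.
* **Scenarios.** Future climates are additive and/or multiplicative shifts
  of the current grid; a zero shift returns the grid unchanged, exactly.
* **Determinism.** A single integer seed fixes everything. Sub-streams are
  derived as `(seed·1103 + stream·12343) mod (2³¹ − 19)` so that adding
  draws to one stage never perturbs another, and identical seeds produce
  byte-identical VCFs.

The benchmark scale — 17 populations of 12 diploids, 450 neutral + 50
adaptive SNPs at β = 2, four independent noise predictors — mirrors a
typical range-wide GBS design. What passing tests show is that the chain
recovers *known* structure of exactly this form at this sample size; they
do not show robustness to ascertainment bias, batch effects, LD, selection
on many small-effect loci, or non-equilibrium demography, none of which
the generator emulates.

## Genotype QC

Filters run in a fixed order — biallelic → heterozygosity → missingness →
MAF — so that per-rule removal counts in the `FilterReport` are
reproducible. For rules that act on independent criteria the final SNP set
does not depend on the order; the attribution of a doubly-failing SNP to a
rule does, hence the documented convention. Defaults (het ≤ 0.70,
missingness ≤ 0.50, pooled MAF ≥ 0.05, biallelic only) are the standard
post-calling thresholds for GBS panels in outcrossing plants; the
heterozygosity screen targets collapsed homeologs/paralogs, which is why
it is computed among non-missing genotypes only. MAF is pooled over all
individuals rather than per-population — the single-threshold phrasing
used in practice — and positions are kept 1-based to match VCF. Sites with
half-calls or non-diploid GT fields are rejected outright rather than
patched.

## Diversity and differentiation

π at a variant site uses the unbiased diploid estimator
`(2n/(2n−1))·2p̂(1−p̂)` and is averaged over variant sites. Because locus
lengths are not part of a VCF, per-bp diversity of assembled loci is *not*
computable here, and the per-variant-site π (0–0.5 scale) is not directly
comparable to per-bp values from assembly-based pipelines — a deliberate
scope decision, stated in the docs. F_IS aggregates as
`1 − mean(Hobs)/mean(He)` (ratio of averages, Nei's unbiased He), the
common multi-locus convention.

Weir–Cockerham θ is built from the original per-locus variance components
a (among populations), b (among individuals within populations) and c
(within individuals), with missing genotypes reducing the per-locus sample
sizes, and combined over loci as Σa/Σ(a+b+c). No additional finite-sample
corrections are applied. The estimator is validated against an
independently coded scalar-loop oracle to 1e-12 on random instances, hits
θ = 1 exactly for fixed opposite alleles, and is invariant to allele-label
swaps. Small negative estimates are legitimate for the estimator; they are
clamped to 0 only when linearizing to θ/(1−θ) distances (an entry of 1
would be an infinite distance and is an error).

## Ordination

PCA mean-imputes missing genotypes per SNP (standard for genotype
ordinations), scales columns to unit variance, and fixes axis signs by
making the largest-|loading| SNP positive. DAPC takes cluster labels as
input — model-based clustering (ADMIXTURE-like) is intentionally out of
scope — or derives them by seeded k-means on the PC scores. The number of
retained PCs defaults to those explaining 90% of variance; posterior
assignments are the softmax of negative squared distances to cluster
centroids in discriminant space. With labels fitted on the same data,
self-assignment under random labels sits slightly above chance (in-sample
optimism of order n_PCs/n); the tests account for that.

## IBD / IBE

Geographic distance defaults to great-circle km (haversine, radius
6371.0088 km) with a planar `euclidean-degrees` option for comparability
with analyses that treat coordinates as Cartesian — at continental scale
the two can rank pairs differently, so the choice is explicit.
Environmental distance standardizes each variable (mean 0, sd 1) before
Euclidean distance, making it unit-free. The Mantel statistic is the
Pearson correlation of upper triangles; the null permutes the second
matrix's row/column order simultaneously; the test is one-sided for
positive association, matching the directional hypotheses these analyses
pose (the two-sided variant would halve none of the reported r values,
only inflate p). At n ≤ 8 an exhaustive mode enumerates all n!
relabelings, and the sampled version is verified against it.

## Outlier scans

The PC scan regresses each scaled SNP on the first K genotype PCs, forms
the K-vector of regression z-scores, and flags SNPs whose robust
Mahalanobis D² (minimum-covariance-determinant estimate, fixed seed) is
extreme. D² is rescaled by the genomic inflation factor
λ = median(D²)/median(χ²_K) before χ²_K p-values — this is what keeps the
scan calibrated under background structure — and multiple testing is
controlled by Benjamini–Hochberg at FDR 0.01. BH rather than a Storey-type
estimator: with thousands of SNPs and a small true-positive fraction the
two differ little and BH is conservative.

The environmental scan deliberately replaces MCMC machinery with a
deterministic analogue of the same decision variable: standardized
frequencies `(p_kl − p̄_l)/√(p̄_l(1−p̄_l))` give an empirical population
covariance (ridge 1e-6 if not positive definite); each SNP's centered
frequency vector and the standardized environment are whitened by the
inverse Cholesky factor; Spearman ρ between the whitened vectors is the
statistic, with the top 5% of |ρ| flagged and an optional permutation p.
Whitening with an identity covariance reduces exactly to centering, which
pins the implementation. Bayes factors and MCMC convergence diagnostics
are out of scope.

## Gradient forest

The core of the package. Each SNP's population allele-frequency vector is
regressed on the predictors by a random forest (default 2000 trees,
mtry = ⌊p/3⌋, minimum node size 5, bootstrap of populations) implemented
in C++ so that every split's predictor, threshold and impurity improvement
can be recorded. Out-of-bag predictions give the SNP's R²; out-of-bag
permutation gives per-predictor importance. With only ~17 populations as
rows, out-of-bag R² is noisy — which is exactly why SNPs are pre-filtered
to those polymorphic in ≥ 5 populations and why only SNPs with R² > 0
contribute to the aggregation.

Turnover functions are built per predictor on 201 equal-width bins over
the observed range: split improvements are binned at their thresholds,
normalized by the density of observed predictor values (additively
smoothed histogram counts, count + 1 — the smoothing only reshapes within
a SNP, since each SNP's curve is then rescaled to its R²-weighted
importance share `I_sp = R²_s · imp_sp / Σ_p imp_sp`), summed over
positive-R² SNPs and cumulated. By construction F_p is non-decreasing,
F_p(min) = 0, and F_p(max) = I_p, the predictor's overall importance (mean
of I_sp over positive-R² SNPs); these invariants are asserted on every
fit. Permutation importance decides *how much* a predictor matters;
impurity improvements only locate *where* along the gradient the turnover
happens.

Climate grids are transformed through F_p with flat (clamped)
extrapolation outside the fitted range — cumulative importance is
undefined beyond observed splits, so extrapolating any other way would
invent signal. Predictor pruning walks predictors in descending I_p and
keeps those with Pearson |r| ≤ 0.8 against everything already kept. The
PCA→RGB map assigns the first three centered PCs of the composition matrix
to red/green/blue after min–max scaling to [0, 255], with deterministic
sign conventions; rank-deficient compositions fill the missing channels
with neutral gray (128).

## Genetic offset

Offset is the Euclidean distance between current and future compositions
in the *full* transformed space of all retained predictors, not a PCA
reduction — reducing first would discard variance by an arbitrary cutoff
and the distance is well-defined either way. The measure is climate-only:
no migration, plasticity or biotic terms. Offset is symmetric in
(current, future), zero when nothing changes, exactly `a·|Δ|` for a linear
single-predictor turnover `F(x) = a·x`, and non-decreasing in the shift
magnitude for monotone turnover — all asserted, the closed form at 1e-10.

## RDA and variance partitioning

Moran eigenvector maps use the PCNM construction: pairwise distances
truncated at the longest minimum-spanning-tree edge t, weights
`1 − (d/4t)²` within range, double centering, eigendecomposition; positive
eigenvalue eigenvectors are returned orthonormal with Moran's I and a
permutation p each. This reproduces the classical PCNM eigenfunctions
exactly (verified against an independent implementation in the tests) —
including their sinusoidal character on a transect, where the leading
eigenfunction is a broad wave whose rank correlation with the coordinate
is 0.83 for 10 equally spaced sites, not a strictly monotone trend.
"Significant positive spatial structure" is operationalized as Moran's I
above its expectation −1/(n−1) with permutation p ≤ 0.05, keeping up to
the top three eigenfunctions by default.

RDA is multivariate least squares followed by an eigen-summary of the
fitted values; R² is the constrained fraction of total response variance,
adjusted by Ezekiel's formula `1 − (1−R²)(n−1)/(n−p−1)`. A partial RDA
residualizes response and predictors on the conditioning set first and
reports its adjusted fraction as the difference of adjusted R²
(full minus conditioning-only) — the standard convention that makes the
partition ledger sum exactly: env|geo + geo|env + confounded = total
explained (to 1e-10), total explained + unexplained = 1. Permutation
tests use the pseudo-F with row permutation of the response for simple
RDA and permutation of reduced-model residuals for partial RDA; the
confounded fraction has no test, and the table says so with an `NA`.
Forward selection adds the candidate with the largest adjusted-R² gain if
its marginal permutation p ≤ α (default 0.05) and stops when none
qualifies or the cumulative adjusted R² exceeds the global model's
(double stopping). VIF screening iteratively drops the worst column above
10, later-listed columns first on ties, so results are deterministic.
The response matrix convention is per-SNP centered population allele
frequencies.

## Problem sizes and runtime

The test suite and acceptance script run everything at the benchmark scale
chosen for the package: 20-seed replicates for the gradient-forest driver
ranking (full 2000-tree fits), 20 seeds for scan calibration (500-SNP
null panels) and 10 for power (2010-SNP panels), 500 replicates for
Mantel type-I error and adjusted-R² unbiasedness, and lighter 300-tree
fits for the 20-seed offset escalation ladder. These sizes give stable
pass/fail behaviour for the stochastic properties while keeping a full
run in a few minutes on a single core.

## Known limitations

* π is per variant site, not per bp of assembled loci.
* The generator's MCAR missingness and LD-free fragments are idealizations.
* DAPC posterior assignments are in-sample; no cross-validation of the
  retained-PC count is implemented.
* The environmental scan's permutation p-values treat populations as
  exchangeable after whitening; residual structure not captured by the
  covariance estimate would leak into them.
* Offset is a climate-mismatch proxy, not a demographic prediction.
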