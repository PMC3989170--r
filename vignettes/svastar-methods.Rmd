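---
title: "Latent-variable correction for mixed-tissue expression studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable correction for mixed-tissue expression studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Human expression studies — blood, brain, any solid tissue — assay mixtures
of cell types whose proportions differ from subject to subject. A
gene-by-sample matrix $X$ (genes in rows throughout this package) is usually
modelled as

$$X = B S' + E,$$

with $S$ the design matrix (intercept, known covariates, and the primary
factor such as disease status) and $E$ independent noise. In practice the
rows of $E$ are correlated: genetics, sample handling, and above all
cell-type composition affect thousands of genes at once. Surrogate variable
analysis (SVA) models this as

$$X = B S' + \Gamma G' + U,$$

where the columns of $G$ (samples × k) are *surrogate variables* spanning
the latent sources of variation, estimated from the data's own correlation
structure and then used as covariates in per-gene tests.

## Why mixtures break the original iteration

The Leek–Storey algorithm initialises $G$ with the right singular vectors of
the residual $E$ (exactly orthogonal to $S$), then iterates: compute per-gene
p-values for association with the current $G$ ($p_G$, adjusting for
covariates) and for the primary effect ($p_S$, adjusting for covariates and
current SVs); weight each gene by the estimated posterior probability that
it is latent-associated and not primary-associated,
$w = (1-\mathrm{lfdr}(p_G)) \cdot \mathrm{lfdr}(p_S)$; take the SVD of the
row-weighted, row-centred data; keep the first $k$ right singular vectors.

Suppose disease alters expression of a set of genes in *one* cell type of a
three-cell-type mixture. For a gene expressed at similar levels in all cell
types in the control state, control measurements barely depend on the
mixing proportions (they sum to one), but disease measurements become
dominated by the affected cell type and track its proportion. The affected
genes therefore correlate with each other *only within the disease group*.
Under this structure the local-FDR weights drift towards uniformity, the
weighted SVD approaches the plain SVD — which captures all variation
including the group difference — and the returned surrogate variables have
significantly different group means ("heterogeneous" SVs). Adjusting for
them absorbs genuine disease signal and can randomise the gene ranking.

## The SVA* modification

`sva_star()` keeps the identical iteration skeleton but weights genes by
raw p-values instead of posteriors:

$$w_i = p_S(i) \cdot (1 - p_G(i)),$$

with $p_S$ computed by a covariate-preserving *permutation* test
(`permutation_pvalues()`, add-one corrected), because real expression data
contain genes far from normality. A gene with any primary-effect evidence
keeps a proportionally small weight throughout, so surrogate variables may
be non-orthogonal to the groups but cannot become heterogeneous beyond what
chance alone produces in a randomised study. The weight combination is
pluggable (`weight_fun` argument) because only the ingredients — raw
p-values for both effects — are fixed by the method's definition; the
product form is the direct analogue of the posterior product and has the
required endpoint behaviour ($w \to 1$ when $p_S \to 1, p_G \to 0$;
$w \to 0$ when $p_S \to 0$).

Both iterative methods re-test $p_S$ against the *current* SVs each
iteration, mirroring the reference implementation of the original
algorithm; $p_G$ is computed parametrically inside the loop for speed,
permutation being reserved for the primary effect where non-normality
matters most.

## Estimating k

`estimate_k()` uses parallel analysis: the residual's singular values are
compared with the per-component 95th percentile of singular values from 20
null matrices obtained by independently permuting every gene's row of the
data and re-residualising on the same design. Re-residualising matters:
permuting the residual itself destroys its projection geometry and biases
the null low, inflating k on pure noise. k is the count of *leading*
components above their percentile — stopping at the first failure keeps the
false-positive rate at the single-component level (about 5%) instead of
accumulating it across all components. On planted-factor simulations
(loading sd 2.2 vs noise sd 1, 500 genes × 30 samples) the estimator
recovers k ∈ {0, 1, 2} in ≥ 18/20 seeded replicates.

## The mixture simulator

`simulate_mixture_dataset()` generates the benchmark conditions: 1000 genes
in four classes of 250 (noise; group-affected; latent-affected; both), two
groups of 20 samples, three cell types. Construction: pure profiles
$e_{ij} = 2^{\mu_i + \tau_{ij}}$ with a gene baseline $\mu_i \sim
N(7, 1)$ (log2) shared by all cell types and cell-type deviations
$\tau_{ij} \sim N(0, 0.5)$; a disease profile $e^*$ multiplying
cell-type-1 entries of the 500 affected genes by $2^{\delta_i}$ with
per-gene folds $\delta_i \sim$ Exponential(mean 1); Dirichlet(0.5, 0.5,
0.5) mixing proportions per sample; linear-space mixing, then log2; a
uniform latent variable with Normal(0, 0.9) loadings on the latent/both
genes added as an outer product; Normal(0, 0.35) log-scale noise.

Several of these values are the package's own calibration, since the
underlying model fixes only the structure:

* **Shared baseline + deviation profiles.** The mixture mechanism requires
  genes whose control-state expression is similar across cell types; fully
  independent per-cell-type profiles give every gene strong
  proportion-driven variance in both groups, which drowns the
  disease-specific correlation the simulator exists to reproduce. The
  deviation sd of 0.5 log2 keeps most genes within two-fold between cell
  types — typical of real leukocyte profiles — while still imposing a
  global mixture correlation.
* **Heavy-tailed effect sizes.** Real disease signatures contain a few
  strong markers and many weak ones. With identical folds on all affected
  genes, the within-study ranking among true genes is noise-dominated and
  independent studies cannot agree on a top list even in principle;
  exponential folds give studies a shared ranking backbone.
* **Noise and latent scales** (0.35 and 0.9) put the uncorrected t-test AUC
  for discriminating `both` genes from `latent`+`noise` at roughly 0.75–0.9
  — informative but imperfect, leaving the correction room to help or hurt.
* **Dirichlet(0.5, 0.5, 0.5)** spans the several-fold proportion variation
  reported for human blood, with substantial sample-to-sample spread.

The latent variable is drawn independently of the groups: the failure mode
being studied occurs *under perfect randomisation*, which is what makes it
distinctive. `simulate_additive_dataset()` provides the classical favourable
case (iid baselines, additive balanced effects, no mixture) used for
parameter-recovery checks and, with all effects off, for null calibration.
`simulate_compendium()` draws the biology (profiles, disease folds, classes)
once and the nuisance (proportions, latent vector and loadings, noise) per
study — the multi-study setting where correction can improve agreement.

What the simulator does *not* emulate: platform/probe effects, more than
one disease-affected cell type, correlated noise beyond the mixture, or
non-Gaussian heavy-tailed measurement error. Passing tests show the methods
behave as designed under the mixture mechanism, not that they improve any
particular real compendium.

## Cross-study concordance

For each dataset, genes are ranked by a nested F-test (equal to the squared
t-test for two groups) after removing the bottom 20% of genes by mean and
by variance (both cuts on the pre-filter universe; the union is removed —
about 20–30% in practice since the criteria overlap). The top 5% of each
list (ceiling) is scored against every other dataset with the upper-tail
hypergeometric probability $p(k, m, n, N)$, where candidate lists are cut
on each dataset's own universe first and then restricted to the shared
post-filter universe to give $m$ and $n$.

Because genes are dependent, that probability is not a p-value; it is
calibrated per dataset pair against a null built by permuting each
dataset's primary labels (covariates kept attached), re-running the entire
pipeline — including SV re-estimation — 20 times per dataset, and crossing
the permuted rankings (20 × 20 = 400 null scores per pair). The empirical
p-value is the add-one rank of the observed score among the nulls, in
$(0, 1]$ so it log-transforms safely. Methods are compared across the same
pairs with a one-sided Wilcoxon signed-rank test on log empirical p-values.

The packaged concordance experiment uses six studies of 6+6 samples sharing
one biology. Small studies mirror the compendia that motivate the method
(typically 4–20 subjects per group); at 20+20 samples every pair saturates
the 1/401 empirical-p floor for all methods and the comparison degenerates
to ties.

## Numerical conventions

* Ties in rankings break by (p-value, |statistic| descending, gene id);
  quantile-filter ties break by gene id; SV columns are unit-norm with the
  largest-magnitude loading positive — all so results reproduce bit-for-bit
  across runs and BLAS backends.
* Zero-variance genes receive p = 1 everywhere rather than NA.
* Permutation p-values use the add-one correction and are never zero.
* Local FDR: Storey $\pi_0$ from the flat tail above 0.8, probit-scale
  kernel density ratio smoothed by a spline, truncated to [0, 1], forced
  monotone in p. If estimation fails (degenerate p histogram) the iteration
  falls back to uniform weights with a warning — uniform weights reproduce
  the plain-SVD limit rather than silently stopping.
* k is estimated once from the residual and held fixed across iterations.
* Per-repeat seeds in benchmarks derive as `base_seed + repeat`; every
  stochastic function takes an explicit seed and restores the caller's RNG
  state.

## Problem sizes

The shipped tests and the acceptance script run the benchmark at the design
scale (1000 genes, 4 × 250 classes, 20 + 20 samples, 20 repeats), the
concordance experiment on ten 6-study compendia of 6 + 6 samples, and null
calibration on ten 4-study pure-noise compendia — sizes chosen so the full
mechanism (including 400-score permutation nulls per pair with SV
re-estimation) is exercised end to end on a single CPU in minutes.

## Known limitations

* The weight formula for SVA* fixes one of several defensible combinations
  of the two raw p-values; alternatives plug in via `weight_fun`.
* With very strong latent structure relative to the group effect, the
  original posterior weighting can work well; SVA*'s advantage is the
  mixture regime where differential expression is confounded with
  correlation structure under randomisation.
* The concordance framework measures agreement, not truth: systematically
  shared artefacts across studies would also raise it. The permutation null
  protects against dependence within datasets, not against shared biases
  between them.
* Real-compendium preprocessing (array normalisation, probe annotation
  quality) is out of scope; the package consumes already-normalised
  log-scale matrices.
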