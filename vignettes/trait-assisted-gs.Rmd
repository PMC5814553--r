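---
title: "Methods: two-stage spatial adjustment and trait-assisted GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage spatial adjustment and trait-assisted GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in `tagsel`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical design
choices a maintainer should know about.

## The problem

Biomass yield in an energy crop is expensive to phenotype (whole-plot
harvests) and typically shows low genomic heritability, while correlated
traits — plant height at monthly intervals, moisture, or the area under the
height growth curve — are cheap and highly heritable. The package asks: how
much does each way of using those correlated traits improve marker-based
prediction of the focal trait? Five strategies are compared under one
cross-validation design:

| strategy | training data | validation prediction |
|---|---|---|
| standard | focal (80%) | focal GEBV |
| indirect | secondary (80%) | secondary GEBV vs focal x̄ |
| multi-trait indirect | two secondaries (80%) | weighted GEBV index vs focal x̄ |
| multi-trait | focal (80%) + secondary (80%) | focal GEBV |
| trait-assisted | focal (80%) + secondary (100%) | focal GEBV |

Trait-assisted GS differs from multi-trait GS only in that the secondary
records of the *validation* genotypes are kept in the model. Information
then flows to a validation genotype's focal breeding value through its own
secondary phenotype (via the genetic and residual covariances), not only
through its genomic relationship to the training set.

## Stage 1: spatial adjustment

Each trial (year) is analysed separately per trait with
`y = mu + genotype (fixed) + block (random, iid) + e`, where the residual
field over the `row x column` plot grid has separable covariance
`sigma_e^2 * AR1(rho_row) (x) AR1(rho_col)`. Genotype effects are fixed
because the stage-1 output is an adjusted mean (BLUE) per genotype, to be
carried into stage 2; treating checks like any other genotype keeps the
estimable functions simple.

* REML is evaluated on error contrasts (`K'y` with `K` an orthonormal basis
  of the null space of the fixed-effects design), with the residual scale
  profiled out. Two algebraically identical evaluation routes are kept: the
  contrast route, cheap when the genotype design leaves few residual
  degrees of freedom (augmented designs), and a direct Cholesky route with
  the constant `log|X'X|` subtracted, cheap when fixed effects are few
  (replicated designs). A unit test asserts their equality, and the whole
  likelihood is verified against a dense textbook oracle on a 6x6 grid.
* Optimisation is over `(log gamma, atanh rho_row, atanh rho_col)` with
  `gamma = sigma_b^2/sigma_e^2`. The `rho` starting grid `{0, +/-0.5}^2` is
  screened by direct likelihood evaluation and the best point seeds a
  Nelder-Mead run (relative tolerance 1e-10). Missing plots are handled by
  subsetting the separable covariance to observed cells.
* Model choice is by `AIC = -2 loglik + 2 * n_variance_params` among
  candidates sharing identical fixed effects (REML likelihoods are not
  comparable otherwise); ties break toward fewer parameters, then candidate
  order.
* Multi-year combination: per-year BLUEs are standardized (centre, divide
  by the year's SD of BLUEs) by default before averaging per genotype;
  `center` and `none` modes are available because "scaling" conventions
  differ between programs, and single-year analyses are unaffected.

A caveat worth knowing: in an augmented design with mostly unreplicated
entries, the genotype fixed effects absorb almost all degrees of freedom
(e.g. 18 residual df from 435 plots), so the spatial variance parameters
are weakly identified in any single trial. The recovery experiments in the
tests therefore use a replicated layout (24 genotypes x 20 blocks on the
same 480-plot, 12 x 40 grid), where the parameters are identifiable.

## Stage 2: GBLUP

**Relationship matrix.** VanRaden method 1: centre each marker by twice its
(data-estimated) allele frequency and scale the cross-product by
`2 * sum p_k (1 - p_k)` over polymorphic markers. Dosage orientation is
irrelevant after centring (asserted by a test). The matrix is never
modified in storage; a ridge of 1e-6 is added to the diagonal only at solve
time.

**Univariate REML** profiles the total variance and maximises over the
variance ratio with a single eigendecomposition of the observed submatrix
of `A`; golden-section search on (1e-6, 1-1e-6) cannot fail to converge.
Unobserved genotypes receive predictions through `A` (the conditional
expectation route `A_qo (A_oo + ridge I)^{-1} g_o` is proven identical to
the joint missing-record solve by a test).

**Bivariate REML.** The spec of the two-trait model is the classic
unstructured-`G`, unstructured-`R` multivariate GBLUP. The likelihood is
evaluated exactly for arbitrary per-cell missingness with one
eigendecomposition of `A` per data set: rotating by the eigenvectors turns
the complete-data covariance into independent 2x2 blocks `d_i G + R`, and
the observed-record covariance is recovered by Schur-complement downdating
of the inverse at the missing cells,

    V_obs^{-1} = [Q - Q[, m] Q[m, m]^{-1} Q[m, ]]_obs,
    log det V_obs = log det V_full + log det Q[m, m],

with `Q` the (block-diagonal) inverse of the complete covariance. Each REML
evaluation is then `O(n * n_mis^2)` rather than a dense Cholesky of all
records, which is what makes per-fold re-estimation inside cross-validation
affordable on one CPU. The evaluation is verified against a dense oracle.

Maximisation is direct: Nelder-Mead over `(log variances, Fisher-z
correlations)` — a parameterisation that keeps `G` and `R` positive
definite, so no "bending" is ever needed — with restarts from the incumbent
until stable and an optional coordinate-wise golden-section polish. An
EM-style update sequence was deliberately not used: each EM iteration needs
a full mixed-model-equation inverse for its traces, which costs more than
an entire direct fit here, and the direct route inherits a simple
guarantee that replaces EM monotonicity (the returned log-likelihood is
never below the starting value; asserted by a property test).

Two facts about this likelihood surface are worth recording. First, with a
low-heritability focal trait the profile in `cor_g` can be extremely flat
(trading `cor_g` up against `sigma_g,focal` down moves the log-likelihood
by less than 0.5 units), so point estimates of `cor_g` near the boundary do
occur at small `n`; predictions are essentially unaffected because the
implied covariance `cor_g * sqrt(g11 g22)` is what the data pin down.
Second, at a saturated correlation the Fisher-z direction has zero
curvature; the delta-method standard errors therefore use an eigen
pseudo-inverse of the numerically differentiated observed information, and
the `(1 - cor^2)` delta factor correctly reports a near-zero SE there.

**Genomic heritability** is reported as `sigma_g^2 / (sigma_g^2 +
sigma_e^2)`, the component-scale ratio relative to `A` as supplied. For an
inbred panel under VanRaden scaling the mean diagonal of `A` is about 2, so
the realized additive share of phenotypic variance is about
`2 h2_g / (1 + h2_g)` — an `h2_g` of 0.26 corresponds to roughly 41% of the
variance of the adjusted means being additive. The simulator uses the same
convention (below), so estimates are directly comparable to configured
values.

## Cross-validation protocol

* One `cv_scheme` object (balanced random partitions, fold sizes differing
  by at most one) is built per run and passed to every strategy, so all
  strategies see byte-identical folds; a test asserts this.
* Accuracy is ONE pooled Pearson correlation per repeat, computed over all
  genotypes' out-of-fold predictions — never an average of per-fold
  correlations. A crafted counter-example in the tests (per-fold
  correlations of -1, pooled correlation near +1) keeps the two protocols
  from being silently conflated.
* Variance components are re-estimated from each fold's training records
  (for trait-assisted: focal training records plus all secondary records),
  avoiding leakage of validation focal records; a `components =
  "full_data"` flag allows the cheaper convention for comparison. Warm
  starts from the previous fold's estimates only change where the
  optimiser starts, not what it maximises.
* The indirect index standardizes each secondary GEBV vector and weights by
  its genetic correlation with the focal trait, estimated by bivariate REML
  on the training records of each fold and averaged within a repeat.
* The training-fraction sweep draws fresh random subsets per repeat rather
  than inverting folds; fractions leaving fewer than 30 training records
  are skipped with a warning.

## The synthetic-data generator

The generator is the package's study-condition definition, not a
convenience fixture. It emulates:

* a panel of inbred lines (dosages in {0, 2}; heterozygous mode by flag)
  scored at thousands of biallelic SNPs with allele frequencies uniform on
  a configurable MAF band;
* hierarchical population structure: genotypes belong to subpopulations
  ("families") whose marker frequencies are Balding-Nichols draws around
  the panel frequency with dispersion `fst`. Defaults: families of about
  12 and `fst = 0.75`. These were chosen so that a GBLUP analysis of the
  simulated panel reproduces the accuracy regime reported for real,
  strongly structured diversity panels: standard-GS accuracy near 0.4-0.5
  for an `h2_g = 0.26` trait, with the secondary trait's accuracy only
  modestly higher despite `h2_g = 0.9`. Without relatedness between
  training and validation genotypes (`fst = 0`), standard GS on a
  low-heritability trait is nearly useless and indirect GS overtakes it —
  a qualitatively different regime from structured breeding panels;
* multi-trait genetic architecture: effects at `n_qtl` random markers
  (default `min(500, p)`; infinitesimal mode available) drawn with
  covariance proportional to the configured genetic correlation matrix.
  Breeding values and residuals are then *recolored to their exact target
  covariances* (between-family and within-family strata separately, in
  proportion `fst : 1 - fst`), so realized heritabilities and correlations
  do not drift with the QTL draw. Heritabilities are configured on the
  GBLUP component scale described above; total phenotypic variance is 1
  per trait, making heritability the only scale parameter;
* field trials: RCBD or augmented row-column layouts with iid block
  effects and a residual field sampled from the exact separable
  AR(1) x AR(1) covariance via the Kronecker Cholesky identity (validated
  distributionally against a dense-covariance oracle).

What it does **not** emulate: linkage disequilibrium along chromosomes,
maturity- or lodging-like confounders, genotype-by-year interaction, or
selection over cycles. Passing tests therefore demonstrate that the
*machinery* (REML, BLUP, CV bookkeeping) behaves correctly and that the
strategy ranking holds under the assumed covariance structure — not that
any particular accuracy value will be observed on a specific real panel.

## Problem sizes used in tests

The statistical acceptance experiments run at: 453 genotypes x 5000 markers
(heritability recovery, 30 replicates), 500 genotypes (genetic-correlation
recovery, 30 replicates), a 480-plot 12 x 40 field layout (spatial
recovery, 30 replicates), and 300 genotypes x 3000 markers with 30 CV
repeats for the five-strategy comparison — sizes at which each experiment's
Monte-Carlo error is well below the tolerances being asserted while a full
test run stays comfortably interactive.

## Known limitations

* Exactly two traits per multivariate model; an index (e.g. the growth-curve
  AUC) is the way to fold in more phenotypes.
* Stage 1 supports iid and AR(1) x AR(1) residuals only; no splines,
  nugget-plus-AR models, or variogram diagnostics.
* Delta-method standard errors use a finite-difference observed
  information; they are approximations and are flagged as such.
* The coincidence index uses rounded `T` and `R` counts; for very small
  panels `T <= R` makes the index undefined and an error is raised.
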