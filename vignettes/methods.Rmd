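---
title: "Methods: hierarchical areal risk mapping in aremap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical areal risk mapping in aremap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`aremap` estimates small-area relative risks from count data. Counts follow
a Poisson (optionally negative-binomial) likelihood with a log link and an
offset of expected counts,

$$Y_i \sim \mathrm{Poisson}(E_i\,\theta_i), \qquad
\log\theta_i = \beta_0 + x_i^\top\beta + b_i,$$

where $\theta_i$ is the relative risk of area $i$ against the internally
standardized expectation $E_i = \mathrm{pop}_i \cdot \sum_i Y_i / \sum_i
\mathrm{pop}_i$ (so $\sum E_i = \sum Y_i$ and the raw $Y_i/E_i$ is the
standardized morbidity ratio). How expected counts should be built is a
modelling choice — age standardization would be preferable when stratum
populations are available — and internal standardization by total population
is the package's default because it requires nothing beyond the attribute
table.

The random effect uses the BYM2 parameterization,

$$b = \sigma\left(\sqrt{\phi}\,u^\* + \sqrt{1-\phi}\,v\right),$$

with $v \sim N(0, I)$ and $u^\*$ an intrinsic CAR field: conditionally,
each $u_i$ is Gaussian around the mean of its graph neighbours, giving the
improper precision $Q = D - A$ (the graph Laplacian) on the
queen-contiguity graph. Two choices make $\sigma$ and $\phi$ interpretable:

* **Scaling.** $Q$ is rescaled so the geometric mean of the constrained
  marginal variances is 1 per connected component. Without this, the ICAR
  marginal variances depend on the graph topology and $\phi$ would not be
  comparable across maps. After scaling, $\sigma$ is the marginal SD of the
  combined effect and $\phi \in [0,1]$ its structured fraction.
* **Constraints.** $u^\*$ is constrained to sum to zero within each
  connected component, one linear constraint per component; this removes the
  ICAR null space and leaves the intercept identified. Components of size 1
  (isolated areas) carry no structured effect: their $u$ coordinate is
  pinned at zero and only the unstructured part operates. Islands in real
  maps (or isolates in user-supplied GAL files) are therefore handled
  without special input.

The proper-CAR alternative with a fixed propriety parameter $\rho$
(`car_rho`) is available for the structured-only variant but is not the
default: the intrinsic limit is the field-standard prior and matches the
structured component of BYM.

## Priors

* Marginal SD: penalized-complexity (exponential on $\sigma$), calibrated by
  $P(\sigma > 1) = 0.01$. The scale $U = 1$ says a residual relative-risk
  spread beyond $e^{\pm 2}$ is a priori implausible for chronic-disease
  prevalence; both $U$ and the tail probability are configurable.
* Mixing fraction: the genuine BYM2 PC prior, built from the
  Kullback–Leibler distance of the $\phi$-model from the unstructured base
  model using the eigenvalues of the scaled ICAR generalized inverse, with
  the rate calibrated numerically so $P(\phi < 0.5) = 2/3$ — a mild
  preference for unstructured variation that the data readily overcome.
* Fixed effects: Gaussian with precision 0.001 (SD ≈ 32 on the log-RR
  scale); intercept precision $10^{-6}$. Near-flat, so the no-random-effect
  variant reproduces maximum likelihood (this is tested against the IRLS
  fit).
* Negative-binomial log-dispersion: Gaussian with SD 3, a weakly
  informative default spanning dispersions from essentially-Poisson to
  severely overdispersed.

## Inference: nested Laplace approximation on a hyperparameter grid

The hyperparameters are $\theta = (\log\sigma, \operatorname{logit}\phi)$
(plus log NB dispersion when applicable); the latent field
$z = (b, u^\*, \beta)$ is Gaussian given $\theta$. For fixed $\theta$:

1. The log joint is maximized over $z$ by Newton iteration with sparse
   precision matrices (`Matrix` Cholesky factorizations); the linear
   sum-to-zero constraints are enforced at every step by
   conditioning-by-kriging. Convergence requires the projected gradient's
   max-norm below $10^{-6}$ (at most 100 iterations, with step halving);
   non-convergence is an error reporting the grid coordinates.
2. The Gaussian approximation at the mode yields the Laplace approximation
   to the unnormalized hyperparameter posterior
   $\tilde\pi(\theta\,|\,y) \propto \pi(\theta)\,\pi(z^\*|\theta)\,
   \pi(y|z^\*) / \tilde\pi_G(z^\*|\theta,y)$, all densities taken on the
   constraint subspace (the constrained Gaussian normalizer uses
   $\log\det H$ plus the $\log\det(A H^{-1} A^\top)$ correction).

The mode of $\tilde\pi(\theta|y)$ is located numerically (Brent in one
dimension, Nelder–Mead otherwise), its curvature estimated by central
finite differences, and a regular grid placed at mode $\pm 3$ approximate
SDs with 9 points per dimension (7 for the NB dispersion dimension);
normalized grid values are the integration weights $\Delta_k$. Grid points
whose factorization degenerates numerically (extreme $\sigma$) receive
weight zero rather than aborting the fit.

Posterior marginals of fixed effects are weight-mixed Gaussians across the
grid; means, SDs and quantiles come from the mixture (quantiles by
bisection on the mixture CDF), and each coefficient's `kld` column reports
the Kullback–Leibler divergence of its mixture marginal from a single
moment-matched Gaussian — a diagnostic for how non-Gaussian the marginal
is, mirroring the usual fixed-effect table layout. Per-area quantities
(RR intervals, structured/unstructured field summaries, DIC, WAIC,
aggregated counts) use seeded posterior draws: a grid point sampled by
$\Delta_k$, then the constrained Gaussian conditional via the sparse
Cholesky factor. The simplified-Laplace skewness correction is not
implemented; with the count sizes this package targets the Gaussian
conditional is accurate (the GLM-limit test agrees with IRLS to $10^{-4}$
in coefficients and 2% in SEs), and the `kld` field flags cases where the
mixture departs from Gaussianity.

DIC is $2\bar D - D(\bar\eta)$ (mean posterior deviance, deviance at the
posterior mean linear predictor); WAIC is $-2(\mathrm{lppd} - p_\mathrm{WAIC})$
with the pointwise-variance penalty, computed stably by log-sum-exp. Both
report Monte-Carlo standard errors; both are deterministic given the draw
seed.

## Covariate screening

The funnel mirrors standard exploratory practice for areal regression and
runs, in order: chained-equation imputation (below), a pairwise-correlation
filter, forward selection by BIC, iterative VIF pruning, and an interaction
scan.

* Correlation filter: pairs with $|r|$ strictly above 0.6 are broken by
  dropping the member with the larger mean absolute correlation against the
  remaining variables (ties keep the earlier column). The boundary is
  strict: $r = 0.6$ exactly keeps both.
* Forward BIC: Poisson GLM with the log-expected-count offset, starting
  from intercept-only, adding the largest-BIC-decrease candidate, stopping
  at the first non-improvement. Strict decrease is the stopping rule;
  rank-deficient additions are skipped.
* VIF: $1/(1-R^2_j)$ from OLS of column $j$ on the rest; columns above 10
  leave iteratively, largest first, recomputing after each removal. Exact
  collinearity yields $+\infty$; among tied VIFs the latest column leaves
  first, so derived columns go before their sources.
* Interaction scan: for each unordered pair of retained covariates, a
  negative-binomial GLM with both mains and the product term; Wald p-values
  of the product terms are Benjamini–Hochberg adjusted across the family
  and pairs with adjusted $p < 0.05$ are flagged. Failed fits are excluded
  from the family with a warning. The NB family absorbs the overdispersion
  that the deliberately misspecified scan models (mains only) would
  otherwise convert into spurious interactions.
* Imputation: missing cells start at column means, then each incomplete
  column is regressed on all others (random forest by default, OLS
  optionally) over 10 sweeps, producing a single completed table that feeds
  the mapping model. Rubin-style multiple-imputation pooling is out of
  scope by design: the completed table is model input, not an inferential
  target.

## Cluster statistics

Global Moran's $I$ uses row-standardized weights and full random
relabelling; its pseudo p is two-sided around the analytic expectation
$-1/(n-1)$, with ties (e.g. symmetry-equivalent relabelings) counted as
extreme. Local Moran $I_i$ uses conditional permutation (area $i$ held
fixed, neighbours resampled from the other $n-1$ values without
replacement). The tail is chosen against the analytic conditional
expectation $-\tilde z_i^2 (\sum_j w_{ij})/(n-1)$ and the tail probability
is doubled and capped at 1. The doubling matters: labelling on a raw
one-sided p at level $\alpha$ flags either tail and has size about
$2\alpha$ under exchangeable noise (measured ≈ 10% at $\alpha = 0.05$),
whereas the calibrated p keeps the fraction of flagged areas at about
$\alpha$ — which is what the package's type-I test demands. Quadrant labels
(HH/LL/LH/HL) come from the signs of the standardized value and its lag,
values exactly at the mean counting as Low; labels are assigned only where
the (optionally BH-adjusted) pseudo p is at or below $\alpha$. Defaults:
999 permutations, $\alpha = 0.05$, no FDR.

Getis–Ord Gi\* uses self-included binary weights and the textbook z-score;
hot/cold labels at $|z|$ of 1.96 and 2.58. The statistic is undefined
(returned as `NA` with a warning) for an area whose self-included
neighbourhood spans all $n$ areas, where the denominator vanishes. In the
pipeline, LISA runs on posterior-mean RR and Gi\* on Pearson residuals —
the former finds risk clusters, the latter checks that the model left no
spatial signal behind.

## SD-band tiers

Posterior-mean RRs are expressed in sample-SD units from the centre —
by default the reference risk RR = 1 rather than the sample mean, because
the tier framework is anchored to the national expectation; mean-centring
is a flag. Bands break at ±0.5, ±1.5, ±2.5 (left-closed, right-open
upward). Tiers follow the strict-greater rule: above 1.5 SD tier 1,
(0.5, 1.5] tier 2, (−0.5, 0.5] tier 3, at or below −0.5 below-reference;
the classification is invariant to jointly affine rescaling of RR and
centre, and an exactly-boundary value of 1.5 falls to tier 2 by the strict
inequality.

## The synthetic generator

`simulate_counts()` draws data exactly from the model: a lattice of unit
squares with queen (or rook) contiguity, a scaled constrained ICAR field
sampled exactly by spectral decomposition, IID noise, covariates with a
one-factor correlation structure (pairwise $r = \sqrt{c_j c_k}$ from the
per-covariate loadings $c_j$), optional mixing of the standardized
structured field into covariates (to probe spatial confounding), uniform
populations, and MCAR missingness placed one cell per affected row so that
"missing points" and affected records coincide. Each dataset consumes a
single seeded RNG stream — the structured field, noise, covariates,
populations, counts and mask are drawn in sequence after one `set.seed` —
so replicate datasets with distinct seeds share no randomness. (An earlier
design that derived per-component sub-seeds by offsetting the dataset seed
made consecutive replicates share streams, which measurably distorted
dispersion across seed blocks; the single-stream design removes that class
of artifact.)

Defaults emulate a county-like chronic-disease panel: 20×20 lattice, seven
covariates named for the usual behavioural/environmental candidates with
unit SD, pairwise correlation 0.3 and per-unit log-RRs of typical published
magnitude, combined random-effect SD 0.5 with structured fraction 0.57,
populations uniform on [1000, 10000], baseline rate 0.08 cases per person
(a realistic adult diagnosed-diabetes prevalence), and 1.62% of records
MCAR-missing one covariate cell. The generator reproduces the statistical
structure the model assumes — it does not emulate survey-design noise,
raster-derived exposure smoothing, irregular county geometries, or
spatially varying populations, so passing tests demonstrate correctness of
the machinery, not robustness to those real-data features.

With covariates both mutually correlated and spatially mixed, realized
pairwise correlations become
$r_{jk} = \rho_j\rho_k + \sqrt{(1-\rho_j^2)(1-\rho_k^2)}\,\sqrt{c_jc_k}$
where $\rho_j$ is the covariate's loading on the structured field; the
requested pairwise correlation is exact when spatial mixing is off.

## Numerical choices and degenerate inputs

* Queen contiguity uses an exact vertex-on-segment predicate (tolerance 0
  by default; a snap tolerance exists for sloppy real geometries);
  contiguity is treated as topology, in planar coordinates.
* Latent Newton tolerance $10^{-6}$ on the projected gradient max-norm;
  hyperparameter optimization reltol $10^{-8}$; constraint residuals are
  exactly projected, giving structured-field sums below $10^{-10}$.
* Constant vectors are errors for all cluster statistics (the statistics
  are undefined); zero-SD RR vectors are errors for tiering; rank-deficient
  designs are errors naming the collinear columns; all-missing columns are
  errors for imputation.
* DIC/WAIC draws default to 1000; tests and the acceptance script use
  200–1000 draws and lattices from 8×8 to 20×20 with 8–50 replicates per
  property, sizes chosen to make each property decisive at desk scale.

## Known limitations

* Conditional-level DIC rewards chance overdispersion: on pure-Poisson data
  with large expected counts (hundreds per area), roughly a quarter of
  realizations show Pearson dispersion ≥ 1.1, and the hierarchical variants
  then beat the GLM by more than 2 DIC units even though no latent field
  exists. The effect disappears at moderate counts. WAIC behaves similarly.
  Model choice on near-null data should weigh the mixing-fraction interval
  and the overdispersion statistic alongside DIC — the pipeline reports all
  three.
* The Laplace approximation omits the skewness correction; for rare-disease
  counts (small $E_i$) the `kld` diagnostic should be consulted.
* No spatiotemporal extension, zero-inflated likelihoods, distance-band or
  k-nearest-neighbour weights; the contiguity model is queen/rook only.
* The interaction scan tests product terms only, pairwise; higher-order
  structure is out of scope.
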