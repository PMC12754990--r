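# aremap

Bayesian disease mapping for areal count data — county-level relative-risk
estimation with spatially structured random effects, written for
epidemiologists and spatial statisticians who need a self-contained,
reproducible pipeline from raw attribute tables to risk tiers and hotspot
maps.

## The model

Observed case counts in areas `i = 1..n` follow

```
Y_i ~ Poisson(E_i * theta_i)
log(theta_i) = beta_0 + x_i' beta + b_i
```

where `E_i` are internally standardized expected counts
(`E_i = pop_i * sum(Y)/sum(pop)`), `theta_i` is the area's relative risk
(RR), and `b_i` is the BYM2 random effect

```
b = sigma * ( sqrt(phi) * u  +  sqrt(1 - phi) * v )
```

with `u` an intrinsic CAR (ICAR) field on the queen-contiguity graph,
variance-scaled so its geometric-mean marginal variance is 1 and constrained
to sum to zero per connected component, `v` IID standard normal, `sigma` the
marginal SD of the combined effect and `phi` the structured fraction.
Penalized-complexity priors are used for both hyperparameters
(`P(sigma > 1) = 0.01`; `P(phi < 0.5) = 2/3`).

Inference is a nested Laplace approximation implemented on sparse precision
matrices: for each point of a regular grid in `(log sigma, logit phi)` the
latent field is maximized by constrained Newton iteration, a Gaussian
approximation is formed at the mode, and the Laplace-approximate
hyperparameter posterior supplies normalized grid weights; latent marginals
are weight-mixed Gaussians and posterior draws feed DIC, WAIC, per-area RR
intervals and count aggregation. Four model variants (GLM / IID / ICAR /
BYM; Poisson or negative binomial) are compared by DIC and WAIC.

Around the model sit the standard disease-mapping stages: a covariate
screening funnel (pairwise `|r| > 0.6` filter, forward-BIC selection,
iterative VIF > 10 pruning, an FDR-controlled negative-binomial interaction
scan, and chained-equation imputation with a random-forest regressor),
spatial-confounding diagnostics (fixed-effect RR deltas between IID and BYM
fits, field-covariate correlations), global and local Moran's I with
conditional-permutation inference, Getis–Ord Gi* on residuals, and SD-band
risk tiering (tier 1 above +1.5 SD, tier 2 in (0.5, 1.5], tier 3 in
(−0.5, 0.5], centred on the reference risk RR = 1).

A synthetic areal-data generator with known ground truth (lattice
geometries, controllable covariate correlation, structured/unstructured
mixing, MCAR missingness) makes every stage testable without external data.

## Worked example

```r
library(aremap)

cfg <- pipeline_config(
  simulation = simulation_config(n_rows = 10, n_cols = 10,
                                 beta = c(intercept = 0, x1 = 0.2, x2 = -0.1),
                                 sigma = 0.6, phi = 0.8,
                                 missing_fraction = 0.02),
  output_dir = "run1", seed = 11,
  grid_points = 5, nb_grid_points = 5, n_draws = 500, permutations = 199)
res <- run_pipeline(cfg)

res$comparison$table[, c("model", "dic", "waic", "phi_mean", "dic_best")]
#>   model       dic      waic phi_mean dic_best
#> 1   glm 32180.978 34340.635       NA    FALSE
#> 2   iid   989.017   959.862       NA    FALSE
#> 3   car   988.891   961.585       NA     TRUE
#> 4   bym   989.720   961.232 0.767509    FALSE

print(res$fit)
#> posterior_fit: poisson + icar | DIC 988.9 WAIC 961.6
#>                 RR  lower  upper
#> (Intercept) 0.8117 0.8024 0.8210
#> x1          1.2264 1.1144 1.3498
#> x2          0.9624 0.8724 1.0616
```

The comparison table shows the four random-effect variants on a simulated
10×10 lattice with a strong structured field (`phi = 0.8`): the plain GLM
is rejected by ~31,000 DIC units while the three hierarchical variants sit
within one DIC unit of each other — on a single 100-area realization the
data cannot cleanly separate ICAR from BYM, and the intrinsic CAR wins by a
hair; the BYM row still recovers a posterior mixing fraction near the
generating value 0.8. The fit summary prints per-unit RRs for the two
covariates whose true values were exp(0.2) = 1.22 and exp(−0.1) = 0.90. The
output directory contains `per_area.csv` (RR mean and interval, structured
effect, residual, LISA label, SD band, tier per area), `summary.json`
(fixed-effect RR table with Kullback–Leibler diagnostics, model comparison,
residual global Moran, tier counts), and a report GeoJSON for mapping.

Real data enter the same way through `read_area_dataset("areas.geojson",
"attributes.csv")` — a polygon file plus a CSV with `area_id`, `y`,
`population` and covariate columns — or a precomputed GAL contiguity file
via `read_gal()`.

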