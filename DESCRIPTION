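Package: aremap
Title: Bayesian Areal Disease Mapping with Nested-Laplace Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: County-level Bayesian disease mapping for areal count data:
    covariate screening (pairwise-correlation filter, forward-BIC selection,
    VIF pruning, FDR-controlled interaction scan, chained-equation imputation),
    Poisson and negative-binomial hierarchical models with intrinsic CAR,
    IID and BYM2 random effects fitted by a nested Laplace approximation with
    a hyperparameter grid and penalized-complexity priors, model comparison by
    DIC and WAIC, spatial-confounding diagnostics, global and local Moran's I
    with conditional-permutation inference, Getis-Ord Gi* hotspot detection,
    and standard-deviation-band relative-risk tiering. Includes a synthetic
    areal-data generator with known ground truth on lattice geometries, queen
    and rook contiguity builders, GAL and GeoJSON readers and writers, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml,
    ranger
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
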