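test_that("expected counts standardize internally", {
  expect_equal(expected_counts(c(3, 5, 7), rep(10, 3)), rep(5, 3))
  expect_equal(expected_counts(c(10, 30), c(100, 300)), c(10, 30))
  expect_equal(expected_counts(c(8, 2), c(50, 50)), c(5, 5))  # 10 * (50/100)
  expect_error(expected_counts(c(1, 2), c(0, 0)), "population")
})

test_that("the no-random-effect flat-prior limit reproduces the GLM", {
  d <- sim_dataset(8, 8, sigma = 0, phi = 0, seed = 41)
  spec <- model_spec("poisson", "none", beta_precision = 1e-6,
                     intercept_precision = 1e-6)
  fit <- fit_model(d$table, d$graph, spec, n_draws = 500, seed = 2)
  g <- fit_glm(d$table$y, d$table$X, log(d$table$E))
  expect_lt(max(abs(fit$fixed_effects$mean - g$coefficients)), 1e-4)
  expect_lt(max(abs(fit$fixed_effects$sd / sqrt(diag(g$covariance)) - 1)), 0.02)

  # DIC agrees with the analytic AIC in the same limit
  aic <- -2 * g$log_likelihood + 2 * g$k
  expect_lt(abs(fit$dic - aic), 2 * fit$dic_se + 1)
})

test_that("grid weights, constraints and determinism hold on a BYM fit", {
  d <- sim_dataset(8, 8, sigma = 0.6, phi = 0.8, seed = 42)
  spec <- model_spec("poisson", "bym", grid_points = 5)
  f1 <- fit_model(d$table, d$graph, spec, n_draws = 400, seed = 3)
  expect_equal(sum(f1$grid$weights), 1, tolerance = 1e-12)
  expect_equal(which.max(f1$grid$weights), f1$mode_index)
  # posterior-mean structured field sums to ~0 per component
  expect_lt(abs(sum(f1$area_effects$u_mean)), 1e-6)
  # per-area RR intervals bracket the mean
  expect_true(all(f1$rr$lower <= f1$rr$mean & f1$rr$mean <= f1$rr$upper))
  expect_true(all(f1$rr$mean > 0))

  f2 <- fit_model(d$table, d$graph, spec, n_draws = 400, seed = 3)
  expect_identical(f1$dic, f2$dic)
  expect_identical(f1$waic, f2$waic)

  cm <- compare_models(d$table, d$graph,
                       list(a = spec, b = spec), n_draws = 300, seed = 4)
  expect_equal(cm$table$dic[1], cm$table$dic[2])
  expect_equal(cm$table$waic[1], cm$table$waic[2])
})

test_that("relative risks are invariant to the population scale", {
  base <- simulation_config(n_rows = 8, n_cols = 8,
                            beta = c(intercept = 0.1, x1 = 0.3, x2 = -0.2),
                            sigma = 0.3, phi = 0.6, missing_fraction = 0, seed = 55)
  dbl <- base; dbl$baseline_rate <- base$baseline_rate * 2
  fit_of <- function(cfg) {
    d <- simulate_counts(cfg)
    d$table$E <- expected_counts(d$table$y, d$table$population)
    fit_model(d$table, make_lattice(8, 8), model_spec("poisson", "bym", grid_points = 5),
              n_draws = 300, seed = 1)
  }
  f1 <- fit_of(base); f2 <- fit_of(dbl)
  # same latent truth, doubled expected counts: posterior RR fields agree
  expect_gt(cor(f1$rr$mean, f2$rr$mean), 0.95)
  expect_lt(mean(abs(f1$rr$mean - f2$rr$mean)), 0.1)
})

test_that("pearson residuals follow the variance function", {
  fake <- structure(list(y = c(8, 4), E = c(1, 1),
                         fitted_means = c(4, 4),
                         spec = model_spec("poisson", "none")),
                    class = "posterior_fit")
  expect_equal(residuals(fake), c(2, 0))            # (8-4)/sqrt(4), (4-4)/2
  expect_equal(residuals(fake, kind = "raw"), c(4, 0))
})

test_that("posterior count aggregation is additive with calibrated intervals", {
  d <- sim_dataset(8, 8, sigma = 0.4, phi = 0.5, seed = 60)
  fit <- fit_model(d$table, d$graph, model_spec("poisson", "bym", grid_points = 5),
                   n_draws = 500, seed = 5)
  ids <- fit$area_ids
  one <- stats::setNames(rep("all", length(ids)), ids)
  agg1 <- aggregate_posterior_counts(fit, one)
  expect_equal(agg1$mean, sum(fit$fitted_means), tolerance = 1e-8)

  halves <- stats::setNames(rep(c("h1", "h2"), length.out = length(ids)), ids)
  agg2 <- aggregate_posterior_counts(fit, halves)
  expect_equal(sum(agg2$mean), agg1$mean, tolerance = 1e-8)  # additivity per draw
  expect_true(all(agg2$lower <= agg2$mean & agg2$mean <= agg2$upper))

  expect_error(aggregate_posterior_counts(fit, halves[-1]), "unmapped")
})

test_that("the confounding check reports deltas on the RR scale", {
  mini_fit <- function(rr_vals, field) {
    fe <- data.frame(mean = log(rr_vals), row.names = c("(Intercept)", "smoking"))
    structure(list(fixed_effects = fe,
                   covariate_names = c("(Intercept)", "smoking"),
                   area_effects = list(u_mean = field)),
              class = "posterior_fit")
  }
  field <- c(0.1, -0.2, 0.3, -0.2)
  X <- cbind(smoking = c(1, 2, 3, 4))
  cc <- confounding_check(mini_fit(c(1, 1.081), field),
                          mini_fit(c(1, 1.083), field), X)
  expect_equal(cc$delta$rendered, "+0.2%")  # 1.081 -> 1.083
  expect_equal(unname(cc$field_correlations["smoking"]),
               cor(field, X[, 1]))

  cc0 <- confounding_check(mini_fit(c(1, 1.05), field),
                           mini_fit(c(1, 1.05), field), X)
  expect_equal(cc0$delta$pct_change, 0)

  bad <- mini_fit(c(1, 1.05), field)
  bad$covariate_names <- c("(Intercept)", "obesity")
  expect_error(confounding_check(mini_fit(c(1, 1.05), field), bad, X), "mismatch")
})

test_that("well-specified BYM fits leave unstructured residuals", {
  clean <- 0L
  for (s in 1:8) {
    d <- sim_dataset(10, 10, sigma = 0.5, phi = 0.8, seed = 80 + s)
    fit <- fit_model(d$table, d$graph, model_spec("poisson", "bym", grid_points = 5),
                     n_draws = 300, seed = 1)
    r <- residuals(fit)
    names(r) <- fit$area_ids
    gm <- global_moran(r, to_weights(d$graph, "row_standardized"),
                       permutations = 199, seed = s)
    if (gm$pseudo_p > 0.05) clean <- clean + 1L
  }
  expect_gte(clean / 8, 0.75)
})
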