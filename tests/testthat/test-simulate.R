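test_that("ICAR draws are seeded, sum to zero, and match the spectral oracle", {
  g <- make_lattice(4, 4)
  u1 <- sample_icar(g, tau = 1, seed = 9)
  u2 <- sample_icar(g, tau = 1, seed = 9)
  expect_identical(u1, u2)
  expect_error(sample_icar(g, tau = 0), "positive")

  # per-component mean exactly 0 (numerical tolerance) in every draw
  U <- sample_icar(g, tau = 1, seed = 2, n = 100)
  expect_true(all(abs(rowMeans(U)) < 1e-10))

  # path of 3: empirical covariance of 50,000 draws vs the constrained
  # generalized inverse of Q computed by direct eigen-decomposition
  path3 <- area_graph(c("a", "b", "c"), list(a = "b", b = c("a", "c"), c = "b"))
  Q <- rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1))
  e <- eigen(Q, symmetric = TRUE)
  V <- e$vectors[, 1:2]
  pinv <- V %*% diag(1 / e$values[1:2]) %*% t(V)
  draws <- sample_icar(path3, tau = 1, seed = 5, n = 50000)
  expect_lt(max(abs(cov(draws) * (50000 - 1) / 50000 - pinv)), 0.025)
})

test_that("simulated counts have the configured relative-risk structure", {
  # sigma = 0, beta = 0: Poisson mean equals E
  d0 <- sim_dataset(20, 20, beta = c(intercept = 0), sigma = 0, phi = 0, seed = 31)
  E_true <- d0$table$population * 0.08
  ratio <- d0$table$y / E_true
  mc_se <- sqrt(sum(1 / E_true)) / length(E_true)
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se)

  # intercept = log 2: constant RR doubling
  d2 <- sim_dataset(20, 20, beta = c(intercept = log(2)), sigma = 0, phi = 0, seed = 32)
  E2 <- d2$table$population * 0.08
  expect_lt(abs(mean(d2$table$y / E2) - 2), 3 * 2 * sqrt(sum(1 / E2)) / length(E2))
})

test_that("a fully structured field induces positive spatial autocorrelation", {
  # phi = 1, sigma = 1: Moran's I of log-SMR positive with p < 0.05 in
  # at least 90% of seeded replicates (the module's own global_moran as oracle)
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    d <- sim_dataset(10, 10, beta = c(intercept = 0), sigma = 1, phi = 1, seed = 4000 + s)
    v <- log(pmax(d$table$y, 0.5) / d$table$E)
    names(v) <- d$table$area_ids
    gm <- global_moran(v, to_weights(d$graph, "row_standardized"),
                       permutations = 199, seed = s)
    if (gm$I > 0 && gm$pseudo_p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("covariate generator delivers the requested correlations", {
  spec <- data.frame(name = c("x1", "x2", "x3"), sd = c(1, 2, 1),
                     cor = rep(0.3, 3), spatial_cor = 0)
  d <- sim_dataset(25, 40, beta = c(intercept = 0, x1 = 0, x2 = 0, x3 = 0),
                   sigma = 0, phi = 0, seed = 8, covariate_spec = spec)
  R <- cor(d$table$X)
  off <- R[upper.tri(R)]
  expect_true(all(abs(off - 0.3) < 0.05))   # requested pairwise r at N = 1000
  expect_lt(abs(sd(d$table$X[, "x2"]) - 2), 0.2)

  spec_bad <- spec; spec_bad$cor <- c(1.5, 0.3, 0.3)
  expect_error(simulation_config(beta = c(intercept = 0, x1 = 0, x2 = 0, x3 = 0),
                                 covariate_spec = spec_bad),
               "loadings")
})

test_that("equal configs and seeds give bit-identical datasets", {
  cfg <- simulation_config(n_rows = 6, n_cols = 6, seed = 77)
  d1 <- simulate_counts(cfg)
  d2 <- simulate_counts(cfg)
  expect_identical(d1$table$y, d2$table$y)
  expect_identical(d1$table$X, d2$table$X)
  expect_identical(d1$truth$u, d2$truth$u)
  expect_identical(d1$report, d2$report)
})

test_that("with no random effect the marginal counts are exactly Poisson", {
  # pool 16 replicate 25x25 lattices with constant E = 100: 10,000 draws
  ys <- unlist(lapply(1:16, function(s) {
    sim_dataset(25, 25, beta = c(intercept = 0), sigma = 0, phi = 0, seed = 900 + s,
                population_range = c(5000, 5000), baseline_rate = 0.02)$table$y
  }))
  expect_length(ys, 10000)
  breaks <- c(-Inf, qpois(seq(0.1, 0.9, by = 0.1), 100), Inf)
  obs <- table(cut(ys, breaks))
  expp <- diff(c(0, ppois(qpois(seq(0.1, 0.9, by = 0.1), 100), 100), 1))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = expp))
  expect_gt(gof$p.value, 0.01)
})

test_that("missingness injection reproduces the printed audit", {
  tab <- area_data(paste0("a", 1:3142), rep(1, 3142), rep(100, 3142),
                   matrix(rnorm(3142 * 4), ncol = 4))
  inj <- inject_missing(tab, 51 / 3142, seed = 3)
  expect_equal(inj$report$n_rows_affected, 51)
  expect_equal(inj$report$pct_rows, "1.62")

  inj0 <- inject_missing(tab, 0, seed = 3)
  expect_identical(inj0$data$X, tab$X)
  expect_equal(inj0$report$pct_rows, "0.00")

  inj_b <- inject_missing(tab, 51 / 3142, seed = 3)
  expect_identical(inj$data$X, inj_b$data$X)

  expect_error(inject_missing(tab, 1), "fraction")
})

test_that("synthetic datasets round-trip through the external formats", {
  d <- sim_dataset(3, 3, seed = 15, missing_fraction = 0)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(d, dir)
  back <- read_area_dataset(paths[["geometry"]], paths[["attributes"]])
  expect_identical(back$graph$neighbors[d$graph$area_ids], d$graph$neighbors)
  expect_equal(back$table$y[match(d$table$area_ids, back$table$area_ids)], d$table$y)
  expect_equal(back$table$X[match(d$table$area_ids, back$table$area_ids), colnames(d$table$X)],
               d$table$X, ignore_attr = TRUE)
})
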