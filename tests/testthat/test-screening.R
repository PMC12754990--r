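test_that("count GLM recovers closed-form maximum-likelihood estimates", {
  set.seed(1)
  y <- rpois(200, 7)
  f <- fit_glm(y)
  expect_equal(exp(unname(f$coefficients[1])), mean(y), tolerance = 1e-8)

  grp <- rep(0:1, each = 100)
  y2 <- rpois(200, ifelse(grp == 1, 12, 4))
  f2 <- fit_glm(y2, cbind(grp = grp))
  expect_equal(unname(f2$coefficients["grp"]),
               log(mean(y2[grp == 1]) / mean(y2[grp == 0])), tolerance = 1e-8)

  # IRLS score equations at convergence
  X <- cbind(1, grp)
  expect_lt(max(abs(t(X) %*% (y2 - f2$fitted_means))), 1e-6)

  expect_error(fit_glm(y2, cbind(a = grp, b = grp)), "rank deficient")
})

test_that("NB fit on Poisson data collapses to the Poisson fit", {
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  y <- rpois(n, exp(1 + 0.4 * x))
  fp <- fit_glm(y, cbind(x = x))
  fnb <- fit_glm(y, cbind(x = x), family = "negative_binomial")
  expect_lt(max(abs(fp$coefficients - fnb$coefficients)), 0.01)
  # estimated dispersion implies variance/mean < 1.1
  mu <- mean(fnb$fitted_means)
  expect_lt(1 + mu / fnb$dispersion, 1.1)
})

test_that("Pearson overdispersion statistic is calibrated", {
  set.seed(6)
  y <- rpois(5000, exp(0.5))
  f <- fit_glm(y)
  s <- overdispersion_stat(f, y)
  expect_gt(s, 0.9); expect_lt(s, 1.1)

  ynb <- MASS::rnegbin(5000, mu = exp(0.5), theta = 2)
  fnb_pois <- fit_glm(ynb)
  expect_gt(overdispersion_stat(fnb_pois, ynb), 1.3)

  yconst <- rep(4, 50)
  fc <- fit_glm(yconst)  # fitted means identical to y
  expect_equal(overdispersion_stat(fc, yconst), 0)
})

test_that("correlation filter drops one member per violating pair, strictly", {
  set.seed(7)
  n <- 400
  a <- rnorm(n)
  X <- cbind(a = a, b = rnorm(n), a_copy = a)
  cf <- correlation_filter(X)
  expect_equal(cf$dropped$variable, "a_copy")
  expect_setequal(colnames(cf$X), c("a", "b"))

  # mutually orthogonal columns survive
  Xo <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  colnames(Xo) <- c("u", "v", "w")
  expect_equal(nrow(correlation_filter(Xo)$dropped), 0)

  # r = 0.60 exactly: both kept (strict inequality); centred orthonormal basis
  q <- qr.Q(qr(scale(matrix(rnorm(n * 2), n), center = TRUE, scale = FALSE)))
  x1 <- q[, 1]; z <- q[, 2]
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * z
  Xe <- cbind(p = x1, q = x2)
  expect_equal(cor(Xe)[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(nrow(correlation_filter(Xe, 0.6)$dropped), 0)

  expect_error(correlation_filter(cbind(c = rep(1, n), d = rnorm(n))), "constant")
})

test_that("forward-BIC selection finds true predictors and resists noise", {
  hits <- 0L
  sizes <- integer(50)
  for (s in 1:50) {
    set.seed(100 + s)
    n <- 500
    Xc <- matrix(rnorm(n * 6), n, 6,
                 dimnames = list(NULL, c("true", paste0("n", 1:5))))
    y <- rpois(n, exp(0.2 + 0.5 * Xc[, "true"]))
    fb <- forward_bic(y, Xc)
    if ("true" %in% fb$selected) hits <- hits + 1L
    y0 <- rpois(n, exp(0.2))
    sizes[s] <- length(forward_bic(y0, Xc[, -1])$selected)
  }
  expect_gte(hits / 50, 0.9)
  expect_equal(median(sizes), 0)

  # BIC path strictly decreasing; a duplicated copy is never chosen
  set.seed(3)
  n <- 300
  Xd <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x", "x_dup")))
  Xd[, "x_dup"] <- Xd[, "x"]
  yd <- rpois(n, exp(0.3 + 0.6 * Xd[, "x"]))
  fb <- forward_bic(yd, Xd)
  expect_equal(fb$selected, "x")
  expect_true(all(diff(fb$bic_path$bic) < 0))
})

test_that("VIF filter matches the closed form and removes exact collinearity", {
  n <- 400
  Xo <- qr.Q(qr(matrix(rnorm(n * 3), n))) * sqrt(n)
  colnames(Xo) <- c("a", "b", "c")
  v <- vif_filter(Xo)$vif
  expect_true(all(abs(v - 1) < 0.05))

  X2 <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  X3 <- cbind(X2, x3 = X2[, 1] + X2[, 2])
  vf <- vif_filter(X3)
  expect_equal(unname(vf$vif_initial["x3"]), Inf)
  expect_setequal(colnames(vf$X), c("x1", "x2"))

  # r = 0.9 pair: VIF ~ 1/(1 - 0.81) = 5.26
  set.seed(9)
  n <- 5000
  z1 <- rnorm(n)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
  Xr <- cbind(z1 = z1, z2 = z2, ind = rnorm(n))
  vr <- vif_filter(Xr)$vif
  expect_lt(abs(vr["z1"] - 5.26), 0.5)
  expect_lt(abs(vr["z2"] - 5.26), 0.5)
})

test_that("interaction scan flags injected products and controls its family", {
  # power: injected product effect recovered across seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(700 + s)
    n <- 1000
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rpois(n, exp(0.2 + 0.2 * X[, "a"] + 0.3 * X[, "a"] * X[, "b"]))
    sc <- suppressWarnings(interaction_scan(y, X))
    flagged <- sc[sc$kept, c("var1", "var2")]
    if (any(flagged$var1 == "a" & flagged$var2 == "b")) hits <- hits + 1L
  }
  expect_gte(hits / 10, 0.9)

  # BH adjustment invariants on the same scan
  set.seed(11)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  y <- rpois(n, exp(0.1 + 0.2 * X[, 1]))
  sc <- suppressWarnings(interaction_scan(y, X))
  ok <- !is.na(sc$p_raw)
  expect_true(all(sc$p_adjusted[ok] >= sc$p_raw[ok] - 1e-12))
  expect_true(all(sc$p_adjusted[ok] <= 1))
  # column permutation does not change the flagged set
  sc2 <- suppressWarnings(interaction_scan(y, X[, c(3, 1, 4, 2)]))
  key <- function(d) sort(paste(pmin(d$var1, d$var2), pmax(d$var1, d$var2))[d$kept])
  expect_identical(key(sc), key(sc2))
})

test_that("chained-equation imputation is deterministic and beats mean fill", {
  X <- matrix(rnorm(50 * 3), 50, 3)
  expect_identical(impute_chained(X, seed = 1), X)  # no missing cells

  set.seed(13)
  Xm <- X; Xm[c(3, 17, 40), 2] <- NA
  i1 <- impute_chained(Xm, seed = 4)
  i2 <- impute_chained(Xm, seed = 4)
  expect_identical(i1, i2)

  # bivariate Gaussian r = 0.8, 20% MCAR on one column:
  # regression imputation beats mean imputation almost always
  wins <- 0L
  for (s in 1:100) {
    set.seed(2000 + s)
    n <- 200
    x <- rnorm(n)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
    miss <- sample.int(n, 40)
    Xm <- cbind(x = x, y = y)
    Xm[miss, "y"] <- NA
    imp <- impute_chained(Xm, regressor = "linear", seed = s)
    rmse_imp <- sqrt(mean((imp[miss, "y"] - y[miss])^2))
    rmse_mean <- sqrt(mean((mean(y[-miss]) - y[miss])^2))
    if (rmse_imp < rmse_mean) wins <- wins + 1L
  }
  expect_gte(wins / 100, 0.95)

  Xall <- cbind(a = rnorm(5), b = rep(NA_real_, 5))
  expect_error(impute_chained(Xall), "entirely missing")
})

test_that("the screening funnel retains the designed survivor set", {
  set.seed(17)
  n <- 800
  inf1 <- rnorm(n); inf2 <- rnorm(n)
  noise <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(inf1 = inf1, inf2 = inf2,
             inf1_dup = inf1, inf2_dup = inf2, inf1_dup2 = inf1,
             n1 = noise[, 1], n2 = noise[, 2], n3 = noise[, 3],
             combo = (noise[, 1] + noise[, 2] + noise[, 3]) / sqrt(3),
             extra = rnorm(n))
  y <- rpois(n, exp(0.2 + 0.4 * inf1 - 0.3 * inf2))
  rep <- suppressWarnings(screen_covariates(y, X, seed = 2))
  expect_setequal(rep$retained, c("inf1", "inf2"))
  expect_true(all(c("inf1_dup", "inf2_dup", "inf1_dup2") %in%
                    rep$correlation_dropped$variable))
  expect_true(all(diff(rep$bic_path$bic) < 0))
})
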