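#' Internally standardized expected counts
#'
#' `E_i = population_i * (sum(y) / sum(population))`: the count each area
#' would see if the overall rate applied to its population. By construction
#' `sum(E) = sum(y)` exactly, so the ratio `y/E` is the standardized
#' morbidity ratio with reference 1.
#'
#' @param y observed counts.
#' @param population persons at risk.
#' @return positive numeric vector of expected counts.
#' @export
expected_counts <- function(y, population) {
  if (any(population <= 0)) stop("populations must be positive")
  tot <- sum(population)
  if (tot <= 0) stop("zero total population")
  population * (sum(y) / tot)
}

#' Specification of a hierarchical disease-mapping model
#'
#' @param likelihood `"poisson"` or `"negative_binomial"`.
#' @param random_effect `"none"` (plain GLM), `"iid"` (exchangeable area
#'   effect), `"icar"` (intrinsic CAR structured effect only), or `"bym"`
#'   (BYM2: combined effect `sigma * (sqrt(phi) u + sqrt(1-phi) v)` with a
#'   variance-scaled ICAR `u` and IID `v`).
#' @param sd_pc_u,sd_pc_alpha penalized-complexity prior on the marginal SD:
#'   `P(sigma > sd_pc_u) = sd_pc_alpha` (defaults 1 and 0.01).
#' @param phi_pc_u,phi_pc_alpha PC prior on the BYM2 mixing fraction:
#'   `P(phi < phi_pc_u) = phi_pc_alpha` (defaults 0.5 and 2/3).
#' @param beta_precision Gaussian prior precision on non-intercept fixed
#'   effects (default 0.001).
#' @param intercept_precision prior precision on the intercept (default 1e-6).
#' @param grid_points points per hyperparameter dimension of the integration
#'   grid (default 9; minimum 3).
#' @param grid_span half-width of the grid in approximate posterior SDs
#'   (default 3).
#' @param nb_grid_points grid points for the NB log-dispersion dimension
#'   (default 7).
#' @param nb_logdisp_prior_sd SD of the Gaussian prior on the NB
#'   log-dispersion (default 3).
#' @param car_rho optional fixed propriety parameter; when set with
#'   `random_effect = "icar"` the structured precision is the proper CAR
#'   `D - rho * A` instead of the intrinsic limit.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(likelihood = c("poisson", "negative_binomial"),
                       random_effect = c("bym", "iid", "icar", "none"),
                       sd_pc_u = 1, sd_pc_alpha = 0.01,
                       phi_pc_u = 0.5, phi_pc_alpha = 2 / 3,
                       beta_precision = 0.001, intercept_precision = 1e-6,
                       grid_points = 9, grid_span = 3,
                       nb_grid_points = 7, nb_logdisp_prior_sd = 3,
                       car_rho = NULL) {
  likelihood <- match.arg(likelihood)
  random_effect <- match.arg(random_effect)
  if (sd_pc_alpha <= 0 || sd_pc_alpha >= 1 || phi_pc_alpha <= 0 || phi_pc_alpha >= 1) {
    stop("PC prior tail probabilities must lie in (0, 1)")
  }
  if (grid_points < 3) stop("grid resolution must be at least 3 per dimension")
  structure(list(likelihood = likelihood, random_effect = random_effect,
                 sd_pc_u = sd_pc_u, sd_pc_alpha = sd_pc_alpha,
                 phi_pc_u = phi_pc_u, phi_pc_alpha = phi_pc_alpha,
                 beta_precision = beta_precision,
                 intercept_precision = intercept_precision,
                 grid_points = as.integer(grid_points), grid_span = grid_span,
                 nb_grid_points = as.integer(nb_grid_points),
                 nb_logdisp_prior_sd = nb_logdisp_prior_sd,
                 car_rho = car_rho),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", x$likelihood, "likelihood,", x$random_effect, "random effect\n")
  invisible(x)
}

# ---- internal machinery -----------------------------------------------------

# model context: everything fixed across hyperparameter values
.model_context <- function(data, graph, spec) {
  stopifnot(inherits(data, "area_data"), inherits(graph, "area_graph"),
            inherits(spec, "model_spec"))
  if (!identical(data$area_ids, graph$area_ids)) stop("data not aligned to graph")
  if (is.null(data$E)) stop("expected counts E not set; call expected_counts() first")
  if (any(data$E <= 0)) stop("nonpositive expected counts")
  if (anyNA(data$X)) stop("covariates contain missing cells; impute first")
  n <- length(data$area_ids)
  Xf <- cbind(`(Intercept)` = 1, data$X)
  p1 <- ncol(Xf)
  re <- spec$random_effect

  beta_prec <- c(spec$intercept_precision, rep(spec$beta_precision, p1 - 1L))

  comp <- graph$components
  comp_sizes <- table(comp)
  big_comps <- as.integer(names(comp_sizes)[comp_sizes >= 2L])
  isolates <- which(!(comp %in% big_comps))

  need_struct <- re %in% c("icar", "bym")
  Qs <- NULL; struct_rank <- 0L; phi_eigen <- NULL
  if (need_struct) {
    ip <- icar_precision(graph, scaled = TRUE)
    Qs <- ip$Q_scaled
    if (!is.null(spec$car_rho) && re == "icar") {
      A <- to_weights(graph, "binary")
      deg <- lengths(graph$neighbors)
      Qs <- Matrix::Diagonal(n, deg) - spec$car_rho * A
    }
    struct_rank <- (n - length(isolates)) - length(big_comps)
    if (re == "bym") {
      ev <- eigen(as.matrix(Qs), symmetric = TRUE, only.values = TRUE)$values
      w <- numeric(n)
      pos <- ev > 1e-9
      w[pos] <- 1 / ev[pos]
      phi_eigen <- w  # eigenvalues of the generalized inverse (0 on null space)
    }
  }

  # latent layout
  if (re == "none") {
    d <- p1; idx_b <- integer(0); idx_u <- integer(0); idx_beta <- seq_len(p1)
  } else if (re %in% c("iid", "icar")) {
    d <- n + p1; idx_b <- seq_len(n); idx_u <- integer(0); idx_beta <- n + seq_len(p1)
  } else {
    d <- 2L * n + p1; idx_b <- seq_len(n); idx_u <- n + seq_len(n)
    idx_beta <- 2L * n + seq_len(p1)
  }

  # likelihood design: eta = B z
  Bmat <- if (re == "none") {
    Matrix::Matrix(Xf, sparse = TRUE)
  } else if (re %in% c("iid", "icar")) {
    cbind(Matrix::Diagonal(n), Matrix::Matrix(Xf, sparse = TRUE))
  } else {
    cbind(Matrix::Diagonal(n),
          Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0), dims = c(n, n)),
          Matrix::Matrix(Xf, sparse = TRUE))
  }

  # constraints: one sum-to-zero row per >=2-member component, on the
  # structured block (u for bym, b for intrinsic icar)
  Amat <- NULL
  constrained_block <- if (re == "bym") idx_u else if (re == "icar" && is.null(spec$car_rho)) idx_b else integer(0)
  if (length(constrained_block) && length(big_comps)) {
    rows <- integer(0); cols <- integer(0)
    for (r in seq_along(big_comps)) {
      members <- which(comp == big_comps[r])
      rows <- c(rows, rep.int(r, length(members)))
      cols <- c(cols, constrained_block[members])
    }
    Amat <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(length(big_comps), d))
  }

  # PC prior pieces
  lambda_sd <- -log(spec$sd_pc_alpha) / spec$sd_pc_u
  phi_prior <- NULL
  if (re == "bym") phi_prior <- .phi_pc_prior(phi_eigen, spec$phi_pc_u, spec$phi_pc_alpha)

  list(spec = spec, n = n, p1 = p1, d = d, y = data$y, E = data$E, Xf = Xf,
       idx_b = idx_b, idx_u = idx_u, idx_beta = idx_beta,
       B = Bmat, A = Amat, Qs = Qs, beta_prec = beta_prec,
       isolates = isolates, struct_rank = struct_rank,
       lambda_sd = lambda_sd, phi_prior = phi_prior,
       log_offset = log(data$E))
}

# genuine BYM2 PC prior on the mixing fraction: distance from the phi = 0
# base model, d(phi) = sqrt(2 KLD(phi)) computed from the eigenvalues w of
# the constrained generalized inverse of the scaled structured precision,
# with the rate calibrated so that P(phi < u) = alpha.
.phi_pc_prior <- function(w, u, alpha) {
  n <- length(w)
  dist <- function(phi) {
    ev <- phi * w + (1 - phi)
    kld <- 0.5 * (sum(ev) - n - sum(log(pmax(ev, 1e-300))))
    sqrt(pmax(2 * kld, 0))
  }
  lambda <- -log(1 - alpha) / dist(u)  # P(phi < u) = 1 - exp(-lambda d(u)) = alpha
  h <- 1e-5
  logdens <- function(phi) {
    phi <- pmin(pmax(phi, 1e-8), 1 - 1e-8)
    dp <- (dist(pmin(phi + h, 1 - 1e-9)) - dist(pmax(phi - h, 1e-9))) / (2 * h)
    log(lambda) - lambda * dist(phi) + log(pmax(dp, 1e-300))
  }
  list(logdens = logdens, lambda = lambda, dist = dist)
}

# theta vector layout per model: bym -> (log sigma, logit phi [, log nb_disp]);
# iid/icar -> (log sigma [, log nb_disp]); none -> ([log nb_disp])
.theta_dim <- function(ctx) {
  base <- switch(ctx$spec$random_effect, none = 0L, iid = 1L, icar = 1L, bym = 2L)
  base + (ctx$spec$likelihood == "negative_binomial")
}

.theta_unpack <- function(ctx, theta) {
  re <- ctx$spec$random_effect
  out <- list(sigma = NA_real_, phi = NA_real_, nb_disp = NA_real_)
  i <- 0L
  if (re != "none") { i <- i + 1L; out$sigma <- exp(theta[i]) }
  if (re == "bym") { i <- i + 1L; out$phi <- stats::plogis(theta[i]) }
  if (ctx$spec$likelihood == "negative_binomial") { i <- i + 1L; out$nb_disp <- exp(theta[i]) }
  out
}

# prior precision of the latent field plus its theta-dependent log-determinant
.prior_precision <- function(ctx, hp) {
  n <- ctx$n; re <- ctx$spec$random_effect
  pin <- 1e8  # pins structured coordinates of isolated areas at 0
  beta_block <- Matrix::Diagonal(ctx$p1, ctx$beta_prec)
  if (re == "none") {
    return(list(Q = beta_block, ld = 0))
  }
  s2 <- hp$sigma^2
  if (re == "iid") {
    Q <- Matrix::bdiag(Matrix::Diagonal(n, 1 / s2), beta_block)
    return(list(Q = Q, ld = -n * log(s2)))
  }
  if (re == "icar") {
    Qb <- ctx$Qs / s2
    if (length(ctx$isolates)) {
      Qb <- Qb + Matrix::sparseMatrix(i = ctx$isolates, j = ctx$isolates,
                                      x = pin, dims = c(n, n))
    }
    ld <- if (is.null(ctx$spec$car_rho)) -ctx$struct_rank * log(s2) else -n * log(s2)
    return(list(Q = Matrix::bdiag(Qb, beta_block), ld = ld))
  }
  # bym: z = (b, u, beta); b | u ~ N(sigma sqrt(phi) u, sigma^2 (1 - phi) I)
  phi <- hp$phi
  tau_c <- 1 / (s2 * (1 - phi))
  Qbb <- Matrix::Diagonal(n, tau_c)
  Qbu <- Matrix::Diagonal(n, -sqrt(phi) / (hp$sigma * (1 - phi)))
  Quu <- ctx$Qs + Matrix::Diagonal(n, phi / (1 - phi))
  if (length(ctx$isolates)) {
    Quu <- Quu + Matrix::sparseMatrix(i = ctx$isolates, j = ctx$isolates,
                                      x = pin, dims = c(n, n))
  }
  Q <- rbind(cbind(Qbb, Qbu), cbind(Matrix::t(Qbu), Quu))
  Q <- Matrix::bdiag(Q, beta_block)
  list(Q = Q, ld = -n * log(s2 * (1 - phi)))
}

# log hyperprior (theta scale, Jacobians included)
.log_hyperprior <- function(ctx, theta, hp) {
  re <- ctx$spec$random_effect
  lp <- 0
  i <- 0L
  if (re != "none") {
    i <- i + 1L
    lp <- lp + log(ctx$lambda_sd) - ctx$lambda_sd * hp$sigma + theta[i]  # PC(sigma), Jacobian sigma
  }
  if (re == "bym") {
    i <- i + 1L
    lp <- lp + ctx$phi_prior$logdens(hp$phi) + log(hp$phi * (1 - hp$phi))  # Jacobian of logit
  }
  if (ctx$spec$likelihood == "negative_binomial") {
    i <- i + 1L
    lp <- lp + stats::dnorm(theta[i], 0, ctx$spec$nb_logdisp_prior_sd, log = TRUE)
  }
  lp
}

# Poisson / NB log-likelihood and its eta-derivatives
.lik_terms <- function(ctx, eta, hp) {
  mu <- ctx$E * exp(eta)
  if (ctx$spec$likelihood == "poisson") {
    list(ll = sum(stats::dpois(ctx$y, mu, log = TRUE)),
         score = ctx$y - mu, curv = mu)
  } else {
    th <- hp$nb_disp
    list(ll = sum(stats::dnbinom(ctx$y, size = th, mu = mu, log = TRUE)),
         score = (ctx$y - mu) * th / (th + mu),
         curv = mu * th * (th + ctx$y) / (th + mu)^2)
  }
}

# constrained Newton maximization of the log joint at fixed theta.
# Returns mode, Cholesky factor of the negative Hessian, constraint helpers,
# and the pieces of the Laplace hyperparameter posterior.
.inner_mode <- function(ctx, theta, z_start = NULL) {
  hp <- .theta_unpack(ctx, theta)
  pp <- .prior_precision(ctx, hp)
  Qp <- pp$Q
  A <- ctx$A
  z <- if (is.null(z_start)) numeric(ctx$d) else z_start
  if (!is.null(A)) {  # project the warm start onto the constraint
    AAt <- A %*% Matrix::t(A)
    z <- z - as.numeric(Matrix::t(A) %*% Matrix::solve(AAt, A %*% z))
  }
  obj <- function(z, lt) lt$ll - 0.5 * sum(z * as.numeric(Qp %*% z))
  eta <- as.numeric(ctx$B %*% z)
  lt <- .lik_terms(ctx, eta, hp)
  f <- obj(z, lt)
  ch <- NULL
  converged <- FALSE
  for (it in seq_len(100L)) {
    grad <- as.numeric(Matrix::t(ctx$B) %*% lt$score) - as.numeric(Qp %*% z)
    H <- Qp + Matrix::crossprod(ctx$B * sqrt(lt$curv))
    ch <- suppressWarnings(Matrix::Cholesky(Matrix::forceSymmetric(H), LDL = FALSE, perm = TRUE))
    gproj <- grad
    if (!is.null(A)) {
      AAt <- A %*% Matrix::t(A)
      gproj <- grad - as.numeric(Matrix::t(A) %*% Matrix::solve(AAt, A %*% grad))
    }
    if (max(abs(gproj)) < 1e-6) { converged <- TRUE; break }
    step <- as.numeric(Matrix::solve(ch, grad, system = "A"))
    z_new <- z + step
    if (!is.null(A)) {
      W <- Matrix::solve(ch, Matrix::t(A), system = "A")
      S <- as.matrix(A %*% W)
      z_new <- z_new - as.numeric(W %*% solve(S, as.numeric(A %*% z_new)))
    }
    # step halving on objective decrease
    alpha <- 1
    repeat {
      z_try <- z + alpha * (z_new - z)
      eta_try <- as.numeric(ctx$B %*% z_try)
      lt_try <- .lik_terms(ctx, eta_try, hp)
      f_try <- obj(z_try, lt_try)
      if (is.finite(f_try) && (f_try >= f - 1e-10)) break
      alpha <- alpha / 2
      if (alpha < 1e-6) break
    }
    z <- z_try; eta <- eta_try; lt <- lt_try
    if (abs(f_try - f) < 1e-10 && it > 1L) {
      f <- f_try
      # recompute curvature pieces at the accepted point, then test gradient
      grad <- as.numeric(Matrix::t(ctx$B) %*% lt$score) - as.numeric(Qp %*% z)
      gproj <- grad
      if (!is.null(A)) {
        AAt <- A %*% Matrix::t(A)
        gproj <- grad - as.numeric(Matrix::t(A) %*% Matrix::solve(AAt, A %*% grad))
      }
      H <- Qp + Matrix::crossprod(ctx$B * sqrt(lt$curv))
      ch <- suppressWarnings(Matrix::Cholesky(Matrix::forceSymmetric(H), LDL = FALSE, perm = TRUE))
      if (max(abs(gproj)) < 1e-6) converged <- TRUE
      break
    }
    f <- f_try
  }
  if (!converged) {
    # one last check at the current point
    grad <- as.numeric(Matrix::t(ctx$B) %*% lt$score) - as.numeric(Qp %*% z)
    gproj <- grad
    if (!is.null(A)) {
      AAt <- A %*% Matrix::t(A)
      gproj <- grad - as.numeric(Matrix::t(A) %*% Matrix::solve(AAt, A %*% grad))
    }
    if (max(abs(gproj)) >= 1e-6) {
      stop("latent-field Newton iteration did not converge at theta = (",
           paste(signif(theta, 4), collapse = ", "), "); |grad| = ",
           signif(max(abs(gproj)), 3))
    }
    H <- Qp + Matrix::crossprod(ctx$B * sqrt(lt$curv))
    ch <- suppressWarnings(Matrix::Cholesky(Matrix::forceSymmetric(H), LDL = FALSE, perm = TRUE))
  }

  ldet_H <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  ldet_S <- 0
  W <- NULL; S <- NULL
  if (!is.null(A)) {
    W <- Matrix::solve(ch, Matrix::t(A), system = "A")
    S <- as.matrix(A %*% W)
    ldet_S <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  }
  # Laplace approximation to the unnormalized log hyperparameter posterior:
  # log pi(theta) + log pi(z* | theta) + log pi(y | z*) - log piG(z* | theta, y),
  # densities taken on the constraint subspace.
  lp <- .log_hyperprior(ctx, theta, hp) +
    (-0.5 * sum(z * as.numeric(Qp %*% z)) + 0.5 * pp$ld) +
    lt$ll -
    0.5 * (ldet_H + ldet_S)
  list(z = z, eta = eta, hp = hp, ch = ch, W = W, S = S,
       lp = lp, ll = lt$ll, curv = lt$curv, theta = theta)
}

# marginal variance of latent coordinates under the constraint
.latent_variances <- function(ctx, ms, coords) {
  vapply(coords, function(j) {
    e <- numeric(ctx$d); e[j] <- 1
    s <- as.numeric(Matrix::solve(ms$ch, e, system = "A"))
    v <- s[j]
    if (!is.null(ms$W)) {
      wj <- as.numeric(ms$W[j, , drop = FALSE])
      v <- v - drop(t(wj) %*% solve(ms$S, wj))
    }
    max(v, 0)
  }, numeric(1))
}

# one draw matrix (m x d) from the constrained Gaussian at a grid point
.draw_latent <- function(ctx, ms, m) {
  eps <- matrix(stats::rnorm(m * ctx$d), nrow = ctx$d)
  v <- Matrix::solve(ms$ch, eps, system = "Lt")
  z0 <- as.matrix(Matrix::solve(ms$ch, v, system = "Pt"))
  z <- z0 + ms$z
  if (!is.null(ms$W)) {
    Az <- as.matrix(ctx$A %*% z)
    z <- z - as.matrix(ms$W %*% solve(ms$S, Az))
  }
  t(z)
}

# quantile of a Gaussian mixture by bisection on the CDF
.mixture_quantile <- function(w, mu, sd, probs) {
  cdf <- function(x) sum(w * stats::pnorm(x, mu, sd))
  vapply(probs, function(p) {
    lo <- min(mu - 10 * sd); hi <- max(mu + 10 * sd)
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (cdf(mid) < p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

# KL divergence of a Gaussian mixture from its moment-matched Gaussian
.mixture_kld <- function(w, mu, sd) {
  m <- sum(w * mu)
  v <- sum(w * (sd^2 + mu^2)) - m^2
  lo <- min(mu - 8 * sd); hi <- max(mu + 8 * sd)
  x <- seq(lo, hi, length.out = 2001L)
  dx <- x[2L] - x[1L]
  dens <- rowSums(vapply(seq_along(w), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                         numeric(length(x))))
  g <- stats::dnorm(x, m, sqrt(v))
  ok <- dens > 1e-300
  sum(dens[ok] * (log(dens[ok]) - log(pmax(g[ok], 1e-300)))) * dx
}

#' Fit a hierarchical disease-mapping model by nested Laplace approximation
#'
#' For each point of a regular grid in the (transformed) hyperparameters, the
#' mode of the latent field (fixed effects plus constrained random effects)
#' is found by sparse Newton iteration, the Gaussian approximation is formed
#' at the mode, and the Laplace approximation to the unnormalized
#' hyperparameter posterior is evaluated there; grid weights are the
#' normalized values. Latent marginals are weight-mixed Gaussians across the
#' grid. The grid is centred at the hyperparameter mode (found by numerical
#' optimization) and spans `grid_span` approximate posterior SDs per
#' dimension. Posterior draws (grid point sampled by weight, then the
#' constrained Gaussian conditional) feed DIC, WAIC, per-area relative-risk
#' summaries and downstream aggregation.
#'
#' @param data an [area_data] with `E` set and complete covariates.
#' @param graph the aligned [area_graph].
#' @param spec a [model_spec].
#' @param n_draws posterior draws for DIC/WAIC and per-area summaries
#'   (default 1000).
#' @param seed integer seed for the draws.
#' @return object of class `posterior_fit`.
#' @export
fit_model <- function(data, graph, spec, n_draws = 1000L, seed = 1L) {
  ctx <- .model_context(data, graph, spec)
  td <- .theta_dim(ctx)

  # --- hyperparameter mode and grid -----------------------------------------
  warm <- new.env(parent = emptyenv())
  warm$z <- NULL
  lp_fun <- function(theta) {
    ms <- tryCatch(.inner_mode(ctx, theta, warm$z), error = function(e) NULL)
    if (is.null(ms)) return(-Inf)
    warm$z <- ms$z
    ms$lp
  }
  if (td == 0L) {
    grid <- matrix(numeric(0), nrow = 1L, ncol = 0L)
  } else {
    theta0 <- rep(0, td)
    if (spec$random_effect != "none") theta0[1L] <- log(0.3)
    opt <- stats::optim(theta0, function(th) -lp_fun(th),
                        method = if (td == 1L) "Brent" else "Nelder-Mead",
                        lower = if (td == 1L) -12 else -Inf,
                        upper = if (td == 1L) 6 else Inf,
                        control = list(maxit = 400, reltol = 1e-8))
    mode_theta <- opt$par
    h <- 0.05
    Hh <- matrix(0, td, td)
    f0 <- lp_fun(mode_theta)
    for (i in seq_len(td)) {
      for (j in i:td) {
        ei <- ej <- rep(0, td); ei[i] <- h; ej[j] <- h
        if (i == j) {
          Hh[i, i] <- (lp_fun(mode_theta + ei) - 2 * f0 + lp_fun(mode_theta - ei)) / h^2
        } else {
          Hh[i, j] <- Hh[j, i] <-
            (lp_fun(mode_theta + ei + ej) - lp_fun(mode_theta + ei - ej) -
               lp_fun(mode_theta - ei + ej) + lp_fun(mode_theta - ei - ej)) / (4 * h^2)
        }
      }
    }
    Sig <- tryCatch(solve(-Hh), error = function(e) NULL)
    sds <- if (!is.null(Sig) && all(diag(Sig) > 0)) sqrt(diag(Sig)) else rep(0.5, td)
    sds <- pmin(pmax(sds, 0.05), 3)
    axes <- lapply(seq_len(td), function(i) {
      mode_theta[i] + sds[i] * seq(-spec$grid_span, spec$grid_span,
                                   length.out = spec$grid_points)
    })
    if (spec$likelihood == "negative_binomial") {
      axes[[td]] <- mode_theta[td] + sds[td] * seq(-spec$grid_span, spec$grid_span,
                                                   length.out = spec$nb_grid_points)
    }
    grid <- as.matrix(expand.grid(axes))
  }

  # --- evaluate the grid ------------------------------------------------------
  K <- nrow(grid)
  modes <- vector("list", K)
  lps <- numeric(K)
  for (k in seq_len(K)) {
    ms <- tryCatch(.inner_mode(ctx, as.numeric(grid[k, ]), warm$z),
                   error = function(e) NULL)
    if (is.null(ms) || !is.finite(ms$lp)) {
      # numerically degenerate grid point (e.g. extreme sigma): zero weight
      lps[k] <- -Inf
      modes[[k]] <- NA
      next
    }
    warm$z <- ms$z
    modes[[k]] <- ms
    lps[k] <- ms$lp
  }
  if (!any(is.finite(lps))) stop("no valid grid point; non-finite posterior")
  k_ok <- which(is.finite(lps))
  fallback <- modes[[k_ok[which.max(lps[k_ok])]]]
  for (k in seq_len(K)) if (!is.list(modes[[k]])) modes[[k]] <- fallback
  wts <- exp(lps - max(lps))
  wts <- wts / sum(wts)

  # --- analytic mixture marginals for the fixed effects ----------------------
  beta_mu <- t(vapply(modes, function(m) m$z[ctx$idx_beta], numeric(ctx$p1)))
  beta_sd <- t(vapply(modes, function(m) sqrt(.latent_variances(ctx, m, ctx$idx_beta)),
                      numeric(ctx$p1)))
  if (ctx$p1 == 1L) { beta_mu <- matrix(beta_mu, ncol = 1L); beta_sd <- matrix(beta_sd, ncol = 1L) }
  fixed <- data.frame(row.names = colnames(ctx$Xf))
  fixed$mean <- colSums(wts * beta_mu)
  fixed$sd <- sqrt(colSums(wts * (beta_sd^2 + beta_mu^2)) - fixed$mean^2)
  qs <- t(vapply(seq_len(ctx$p1), function(j) {
    .mixture_quantile(wts, beta_mu[, j], beta_sd[, j], c(0.025, 0.5, 0.975))
  }, numeric(3)))
  fixed$q025 <- qs[, 1L]; fixed$q50 <- qs[, 2L]; fixed$q975 <- qs[, 3L]
  fixed$kld <- vapply(seq_len(ctx$p1), function(j) {
    .mixture_kld(wts, beta_mu[, j], beta_sd[, j])
  }, numeric(1))

  # --- posterior draws --------------------------------------------------------
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1L, n_draws, wts))
  Z <- matrix(0, nrow = n_draws, ncol = ctx$d)
  disp_draws <- rep(NA_real_, n_draws)
  pos <- 1L
  for (k in seq_len(K)) {
    if (counts[k] == 0L) next
    zk <- .draw_latent(ctx, modes[[k]], counts[k])
    Z[pos:(pos + counts[k] - 1L), ] <- zk
    disp_draws[pos:(pos + counts[k] - 1L)] <- modes[[k]]$hp$nb_disp
    pos <- pos + counts[k]
  }
  eta_draws <- Z %*% t(as.matrix(ctx$B))
  mu_draws <- sweep(exp(eta_draws), 2L, ctx$E, "*")

  # --- DIC / WAIC -------------------------------------------------------------
  ll_mat <- if (spec$likelihood == "poisson") {
    matrix(stats::dpois(rep(ctx$y, each = n_draws), mu_draws, log = TRUE), nrow = n_draws)
  } else {
    matrix(stats::dnbinom(rep(ctx$y, each = n_draws), size = disp_draws,
                          mu = mu_draws, log = TRUE), nrow = n_draws)
  }
  dev_draws <- -2 * rowSums(ll_mat)
  mean_dev <- mean(dev_draws)
  eta_bar <- colMeans(eta_draws)
  mu_bar_lin <- ctx$E * exp(eta_bar)
  dev_hat <- if (spec$likelihood == "poisson") {
    -2 * sum(stats::dpois(ctx$y, mu_bar_lin, log = TRUE))
  } else {
    -2 * sum(stats::dnbinom(ctx$y, size = sum(wts * vapply(modes, function(m) m$hp$nb_disp, numeric(1))),
                            mu = mu_bar_lin, log = TRUE))
  }
  dic_val <- 2 * mean_dev - dev_hat
  p_dic <- mean_dev - dev_hat
  dic_se <- 2 * stats::sd(dev_draws) / sqrt(n_draws)
  lse <- function(v) { m <- max(v); m + log(mean(exp(v - m))) }  # log-mean-exp
  lppd_i <- apply(ll_mat, 2L, lse)
  var_i <- apply(ll_mat, 2L, stats::var)
  lppd <- sum(lppd_i)
  p_waic <- sum(var_i)
  waic_val <- -2 * (lppd - p_waic)
  waic_se <- stats::sd(-2 * (lppd_i - var_i)) * sqrt(ctx$n) / sqrt(n_draws)

  # --- per-area summaries -----------------------------------------------------
  rr_draws <- exp(eta_draws)
  rr <- data.frame(area_id = data$area_ids,
                   mean = colMeans(rr_draws),
                   lower = apply(rr_draws, 2L, stats::quantile, probs = 0.025),
                   upper = apply(rr_draws, 2L, stats::quantile, probs = 0.975),
                   stringsAsFactors = FALSE)
  area_effects <- data.frame(area_id = data$area_ids, stringsAsFactors = FALSE)
  if (length(ctx$idx_b)) {
    area_effects$b_mean <- colMeans(Z[, ctx$idx_b, drop = FALSE])
    area_effects$b_sd <- apply(Z[, ctx$idx_b, drop = FALSE], 2L, stats::sd)
  }
  if (length(ctx$idx_u)) {
    area_effects$u_mean <- colMeans(Z[, ctx$idx_u, drop = FALSE])
    area_effects$u_sd <- apply(Z[, ctx$idx_u, drop = FALSE], 2L, stats::sd)
  }

  # hyperparameter posterior summaries from the grid
  hyper <- NULL
  if (td > 0L) {
    hps <- t(vapply(modes, function(m) c(sigma = m$hp$sigma, phi = m$hp$phi,
                                         nb_disp = m$hp$nb_disp), numeric(3)))
    hyper <- list()
    for (nm in colnames(hps)) {
      v <- hps[, nm]
      if (all(is.na(v))) next
      ord <- order(v)
      cw <- cumsum(wts[ord])
      q <- function(p) v[ord][which(cw >= p)[1L]]
      hyper[[nm]] <- c(mean = sum(wts * v), q025 = q(0.025), q50 = q(0.5), q975 = q(0.975))
    }
  }

  mu_hat <- colMeans(mu_draws)
  structure(list(spec = spec, area_ids = data$area_ids, y = ctx$y, E = ctx$E,
                 covariate_names = colnames(ctx$Xf),
                 grid = list(theta = grid, log_posterior = lps, weights = wts),
                 fixed_effects = fixed, hyper = hyper,
                 area_effects = area_effects, rr = rr,
                 dic = dic_val, dic_se = dic_se, p_dic = p_dic,
                 waic = waic_val, waic_se = waic_se, p_waic = p_waic,
                 mean_deviance = mean_dev, lppd = lppd,
                 fitted_means = mu_hat,
                 eta_draws = eta_draws, disp_draws = disp_draws,
                 n_draws = n_draws, seed = seed,
                 log_likelihood_at_mode = modes[[which.max(lps)]]$ll,
                 mode_index = which.max(lps)),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat("posterior_fit:", x$spec$likelihood, "+", x$spec$random_effect,
      sprintf("| DIC %.1f WAIC %.1f\n", x$dic, x$waic))
  tab <- x$fixed_effects
  tab_rr <- data.frame(RR = exp(tab$mean), lower = exp(tab$q025), upper = exp(tab$q975),
                       kld = signif(tab$kld, 3), row.names = rownames(tab))
  print(round(tab_rr[, 1:3], 4))
  if (!is.null(x$hyper$phi)) {
    cat(sprintf("mixing fraction phi: %.3f (%.3f-%.3f)\n",
                x$hyper$phi[["mean"]], x$hyper$phi[["q025"]], x$hyper$phi[["q975"]]))
  }
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' `DIC = 2 * mean posterior deviance - deviance at the posterior mean of
#' the linear predictor`, computed from the stored posterior draws; the
#' Monte-Carlo standard error is attached as an attribute.
#' @param fit a [fit_model()] result.
#' @return scalar DIC with attributes `se` and `p_eff`.
#' @export
dic <- function(fit) {
  structure(fit$dic, se = fit$dic_se, p_eff = fit$p_dic)
}

#' Watanabe-Akaike information criterion of a fit
#'
#' `WAIC = -2 (lppd - p_waic)` with the pointwise-variance penalty, from the
#' stored posterior draws.
#' @param fit a [fit_model()] result.
#' @return scalar WAIC with attributes `se` and `p_eff`.
#' @export
waic <- function(fit) {
  structure(fit$waic, se = fit$waic_se, p_eff = fit$p_waic)
}

#' Compare model variants on shared data
#'
#' Fits each specification on the same data/offset and tabulates DIC, WAIC,
#' effective parameters and (where applicable) the posterior mixing-fraction
#' summary, flagging the DIC-best and WAIC-best rows. Failures in one
#' variant are recorded and do not abort the others.
#'
#' @param data an [area_data]; @param graph the aligned [area_graph].
#' @param specs named list of [model_spec]s.
#' @param n_draws,seed passed to [fit_model()].
#' @return list with `table` (data frame) and `fits` (list, NULL on failure).
#' @export
compare_models <- function(data, graph, specs, n_draws = 1000L, seed = 1L) {
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) paste(s$likelihood, s$random_effect, sep = "_"),
                           character(1))
  }
  fits <- vector("list", length(specs)); names(fits) <- names(specs)
  rows <- lapply(names(specs), function(nm) {
    f <- tryCatch(fit_model(data, graph, specs[[nm]], n_draws = n_draws, seed = seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      return(data.frame(model = nm, dic = NA_real_, waic = NA_real_,
                        p_dic = NA_real_, p_waic = NA_real_,
                        phi_mean = NA_real_, phi_q025 = NA_real_, phi_q975 = NA_real_,
                        error = conditionMessage(f), stringsAsFactors = FALSE))
    }
    fits[[nm]] <<- f
    phi <- f$hyper$phi
    data.frame(model = nm, dic = f$dic, waic = f$waic,
               p_dic = f$p_dic, p_waic = f$p_waic,
               phi_mean = if (is.null(phi)) NA_real_ else phi[["mean"]],
               phi_q025 = if (is.null(phi)) NA_real_ else phi[["q025"]],
               phi_q975 = if (is.null(phi)) NA_real_ else phi[["q975"]],
               error = NA_character_, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$dic_best <- !is.na(tab$dic) & tab$dic == min(tab$dic, na.rm = TRUE)
  tab$waic_best <- !is.na(tab$waic) & tab$waic == min(tab$waic, na.rm = TRUE)
  list(table = tab, fits = fits)
}

#' Spatial-confounding diagnostic
#'
#' Compares fixed-effect relative risks between the model without and with
#' the structured effect (IID vs BYM under an identical offset), reporting
#' the percent change per covariate, plus the Pearson correlation of the
#' BYM posterior-mean structured field with each covariate. Small deltas and
#' modest correlations indicate the structured effect is not proxying a
#' covariate.
#'
#' @param fit_iid,fit_bym fits from [fit_model()] on identical data.
#' @param X the covariate matrix used in both fits.
#' @return list with `delta` (data frame: rr_iid, rr_bym, pct_change and its
#'   rendering) and `field_correlations`.
#' @export
confounding_check <- function(fit_iid, fit_bym, X) {
  v1 <- setdiff(fit_iid$covariate_names, "(Intercept)")
  v2 <- setdiff(fit_bym$covariate_names, "(Intercept)")
  if (!identical(sort(v1), sort(v2))) stop("mismatched covariate sets between fits")
  rr_iid <- exp(fit_iid$fixed_effects[v1, "mean"])
  rr_bym <- exp(fit_bym$fixed_effects[v1, "mean"])
  pct <- 100 * (rr_bym - rr_iid) / rr_iid
  delta <- data.frame(variable = v1, rr_iid = rr_iid, rr_bym = rr_bym,
                      pct_change = pct,
                      rendered = sprintf("%+.1f%%", pct),
                      stringsAsFactors = FALSE)
  field <- fit_bym$area_effects$u_mean
  if (is.null(field)) field <- fit_bym$area_effects$b_mean
  fc <- vapply(v1, function(v) stats::cor(field, X[, v]), numeric(1))
  list(delta = delta, field_correlations = fc)
}

#' Per-area residuals of a fit
#'
#' Pearson residuals `(y - mu_hat) / sqrt(V(mu_hat))` with `mu_hat` the
#' posterior mean fitted count and `V` the variance function of the fitted
#' family; or raw residuals.
#'
#' @param object a `posterior_fit`.
#' @param kind `"pearson"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector aligned to the areas.
#' @export
residuals.posterior_fit <- function(object, kind = c("pearson", "raw"), ...) {
  kind <- match.arg(kind)
  mu <- object$fitted_means
  r <- object$y - mu
  if (kind == "raw") return(r)
  v <- if (object$spec$likelihood == "poisson") mu else {
    th <- mean(object$disp_draws)
    mu + mu^2 / th
  }
  r / sqrt(v)
}

#' Aggregate posterior fitted counts over groups of areas
#'
#' Sums the posterior draws of the fitted counts within each group (e.g.
#' counties to states) and reports the posterior mean and 95\% interval of
#' each group total. Additivity holds exactly per draw, so the group means
#' sum to the overall mean.
#'
#' @param fit a `posterior_fit`.
#' @param grouping named character vector mapping every area id to a group.
#' @return data frame with group, mean, lower, upper.
#' @export
aggregate_posterior_counts <- function(fit, grouping) {
  unmapped <- setdiff(fit$area_ids, names(grouping))
  if (length(unmapped)) stop("unmapped areas: ", paste(utils::head(unmapped, 5), collapse = ", "))
  g <- as.character(grouping[fit$area_ids])
  mu_draws <- sweep(exp(fit$eta_draws), 2L, fit$E, "*")
  groups <- unique(g)
  agg <- vapply(groups, function(gr) rowSums(mu_draws[, g == gr, drop = FALSE]),
                numeric(nrow(mu_draws)))
  if (is.null(dim(agg))) agg <- matrix(agg, ncol = length(groups))
  data.frame(group = groups,
             mean = colMeans(agg),
             lower = apply(agg, 2L, stats::quantile, probs = 0.025),
             upper = apply(agg, 2L, stats::quantile, probs = 0.975),
             stringsAsFactors = FALSE)
}
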