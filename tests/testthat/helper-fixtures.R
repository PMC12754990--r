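# shared fixtures and independent oracles used across the suite

# simulated lattice dataset with expected counts set
sim_dataset <- function(n_rows = 10, n_cols = 10,
                        beta = c(intercept = 0, x1 = 0.3, x2 = -0.2),
                        sigma = 0.5, phi = 0.8, seed = 1,
                        missing_fraction = 0, ...) {
  cfg <- simulation_config(n_rows = n_rows, n_cols = n_cols, beta = beta,
                           sigma = sigma, phi = phi,
                           missing_fraction = missing_fraction, seed = seed, ...)
  d <- simulate_counts(cfg)
  d$table$E <- expected_counts(d$table$y, d$table$population)
  d
}

# unit-square polygons for an r x c grid, keyed like make_lattice
square_polys <- function(n_rows, n_cols) {
  make_lattice(n_rows, n_cols)$polygons
}

# direct textbook Gi* recomputation, independent of the package implementation
gistar_direct <- function(values, Wd) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- Wd[i, ]
    num <- sum(w * values) - xbar * sum(w)
    den <- S * sqrt((n * sum(w^2) - sum(w)^2) / (n - 1))
    out[i] <- num / den
  }
  out
}

# exact global Moran permutation tail probability by full enumeration
moran_exact_p <- function(values, Wd) {
  n <- length(values)
  z <- values - mean(values)
  S0 <- sum(Wd)
  I_of <- function(zz) (n / S0) * sum(zz * (Wd %*% zz)) / sum(zz^2)
  I_obs <- I_of(z)
  E_I <- -1 / (n - 1)
  perms <- all_permutations(n)
  I_all <- apply(perms, 1L, function(idx) I_of(z[idx]))
  mean(abs(I_all - E_I) >= abs(I_obs - E_I) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# exact conditional-permutation pseudo p for local Moran at area i, mirroring
# the package convention: tail fixed by the analytic conditional expectation,
# tail probability doubled and capped at 1
local_moran_exact_p <- function(values, Wd, i) {
  n <- length(values)
  m <- mean(values)
  s <- sqrt(sum((values - m)^2) / n)
  zt <- (values - m) / s
  wrow <- Wd[i, ]
  nb <- which(wrow != 0)
  I_obs <- zt[i] * sum(wrow[nb] * zt[nb])
  others <- zt[-i]
  perms <- all_permutations(n - 1L)
  I_all <- apply(perms, 1L, function(idx) zt[i] * sum(wrow[nb] * others[idx][seq_along(nb)]))
  e_cond <- -zt[i]^2 * sum(wrow[nb]) / (n - 1)
  p_tail <- if (I_obs >= e_cond) mean(I_all >= I_obs - 1e-12) else mean(I_all <= I_obs + 1e-12)
  min(1, 2 * p_tail)
}
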