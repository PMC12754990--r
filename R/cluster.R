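#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the mean-centred values and
#' `S0` the sum of all weights. The pseudo p-value is two-sided around the
#' analytic expectation `-1/(n-1)` under full random relabelling:
#' `p = (#{|I_perm - E[I]| >= |I_obs - E[I]|} + 1) / (permutations + 1)`.
#'
#' @param values numeric vector (non-constant) aligned to the weights.
#' @param W weight matrix from [to_weights()] (row-standardized is the
#'   usual choice).
#' @param permutations number of random relabelings (default 999).
#' @param seed integer seed.
#' @return list with `I`, `expectation`, `pseudo_p`, `permutations`.
#' @export
global_moran <- function(values, W, permutations = 999L, seed = 1L) {
  n <- length(values)
  if (stats::sd(values) == 0) stop("Moran's I undefined for a constant vector")
  if (nrow(W) != n) stop("weight matrix not aligned to values")
  z <- values - mean(values)
  S0 <- sum(W)
  I_of <- function(zz) (n / S0) * colSums(zz * as.matrix(W %*% zz)) / colSums(zz^2)
  I_obs <- I_of(matrix(z, ncol = 1L))
  expectation <- -1 / (n - 1)
  set.seed(seed)
  perm <- replicate(permutations, z[sample.int(n)])
  I_perm <- I_of(perm)
  # ties with the observed statistic (e.g. symmetry-equivalent relabelings)
  # count as at least as extreme
  p <- (sum(abs(I_perm - expectation) >= abs(I_obs - expectation) - 1e-12) + 1) /
    (permutations + 1)
  list(I = I_obs, expectation = expectation, pseudo_p = p,
       permutations = permutations)
}

#' Anselin's local Moran (LISA) with conditional-permutation inference
#'
#' `I_i = ztilde_i * sum_j w_ij ztilde_j` with `ztilde` standardized by the
#' population SD of the values. Inference is by conditional permutation: the
#' value at area i is held fixed and its neighbours' values are drawn
#' without replacement from the remaining n-1 values. The tail is chosen
#' against the analytic conditional expectation
#' `E[I_i] = -ztilde_i^2 (sum_j w_ij) / (n - 1)` and the tail probability is
#' doubled (capped at 1), so the reported pseudo p is calibrated: under
#' exchangeable noise about alpha of the areas are flagged at level alpha.
#' Quadrants (HH/LL/LH/HL) come from the
#' signs of `ztilde_i` and its spatial lag, values exactly at the mean
#' counting as Low; labels are only assigned where the (optionally
#' FDR-adjusted) pseudo p is at or below `alpha`.
#'
#' @param values numeric vector, non-constant.
#' @param W row-standardized weight matrix.
#' @param permutations conditional permutations per area (default 999).
#' @param alpha significance level for labelling (default 0.05).
#' @param fdr apply Benjamini-Hochberg across areas before labelling.
#' @param seed integer seed.
#' @return object of class `cluster_result`: data frame per area plus
#'   settings.
#' @export
local_moran <- function(values, W, permutations = 999L, alpha = 0.05,
                        fdr = FALSE, seed = 1L) {
  n <- length(values)
  if (stats::sd(values) == 0) stop("local Moran undefined for a constant vector")
  m <- mean(values)
  s_pop <- sqrt(sum((values - m)^2) / n)
  zt <- (values - m) / s_pop
  Wd <- as.matrix(W)
  lag <- as.numeric(Wd %*% zt)
  I_i <- zt * lag
  set.seed(seed)
  p <- rep(NA_real_, n)
  no_neigh <- rowSums(Wd != 0) == 0
  for (i in seq_len(n)) {
    if (no_neigh[i]) next
    wrow <- Wd[i, ]
    nb <- which(wrow != 0)
    others <- zt[-i]
    # draw neighbour sets without replacement from the n-1 other values
    draws <- matrix(0, nrow = permutations, ncol = length(nb))
    for (r in seq_len(permutations)) {
      draws[r, ] <- others[sample.int(n - 1L, length(nb))]
    }
    lag_perm <- draws %*% wrow[nb]
    I_perm <- zt[i] * lag_perm
    # analytic conditional expectation fixes the tail deterministically
    e_cond <- -zt[i]^2 * sum(wrow[nb]) / (n - 1)
    p_tail <- if (I_i[i] >= e_cond) {
      (sum(I_perm >= I_i[i] - 1e-12) + 1) / (permutations + 1)
    } else {
      (sum(I_perm <= I_i[i] + 1e-12) + 1) / (permutations + 1)
    }
    p[i] <- min(1, 2 * p_tail)
  }
  p_eff <- p
  if (fdr) p_eff[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  quadrant <- ifelse(zt > 0,
                     ifelse(lag > 0, "HH", "HL"),
                     ifelse(lag > 0, "LH", "LL"))
  label <- ifelse(!is.na(p_eff) & p_eff <= alpha, quadrant, "not-significant")
  label[no_neigh] <- "not-significant"
  res <- data.frame(area_id = if (!is.null(names(values))) names(values) else rownames(Wd),
                    statistic = I_i, pseudo_p = p, p_adjusted = p_eff,
                    quadrant = quadrant, label = label,
                    isolated = no_neigh, stringsAsFactors = FALSE)
  structure(list(table = res, statistic = "local_moran",
                 settings = list(permutations = permutations, alpha = alpha,
                                 fdr = fdr, seed = seed)),
            class = "cluster_result")
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' The standard Gi* z-score with self-included weights:
#' `(sum_j w_ij x_j - xbar * sum_j w_ij) / (S * sqrt((n * sum w^2 - (sum w)^2) / (n - 1)))`
#' per area, where `xbar` and `S` are the global mean and SD. Areas are
#' labelled hot/cold at |z| thresholds 1.96 (p ~ 0.05) and 2.58 (p ~ 0.01).
#'
#' @param values numeric vector, non-constant, `n >= 3`.
#' @param W self-included binary weight matrix (see [to_weights()]).
#' @return object of class `cluster_result` with per-area z-scores and
#'   labels.
#' @export
getis_ord_gistar <- function(values, W) {
  n <- length(values)
  if (n < 3L) stop("Gi* needs at least 3 areas")
  if (stats::sd(values) == 0) stop("Gi* undefined for a constant vector")
  Wd <- as.matrix(W)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  wx <- as.numeric(Wd %*% values)
  w_sum <- rowSums(Wd)
  w2_sum <- rowSums(Wd^2)
  denom <- S * sqrt(pmax(n * w2_sum - w_sum^2, 0) / (n - 1))
  zscore <- ifelse(denom > 0, (wx - xbar * w_sum) / denom, NA_real_)
  if (anyNA(zscore)) {
    warning("Gi* undefined for area(s) whose neighborhood spans all areas")
  }
  label <- rep("not-significant", n)
  label[which(zscore >= 1.96)] <- "hot-95"
  label[which(zscore >= 2.58)] <- "hot-99"
  label[which(zscore <= -1.96)] <- "cold-95"
  label[which(zscore <= -2.58)] <- "cold-99"
  res <- data.frame(area_id = if (!is.null(names(values))) names(values) else rownames(Wd),
                    statistic = zscore, label = label, stringsAsFactors = FALSE)
  structure(list(table = res, statistic = "gi_star",
                 settings = list(thresholds = c(1.96, 2.58))),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result (", x$statistic, "): ", nrow(x$table), " areas; labels: ",
      paste(names(table(x$table$label)), table(x$table$label), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
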