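#' Fit a Poisson or negative-binomial count GLM
#'
#' Maximum likelihood by iteratively reweighted least squares; the
#' negative-binomial dispersion is profiled by alternating univariate
#' likelihood maximization with IRLS to joint convergence. An intercept is
#' always included; `X` supplies the non-intercept columns.
#'
#' @param y nonnegative integer counts.
#' @param X numeric covariate matrix (may have zero columns).
#' @param offset_log per-observation log offset (e.g. `log(E)`); default 0.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @return object of class `glm_fit`: coefficients, covariance, dispersion
#'   (`theta`, NB only), log-likelihood, fitted means, and the underlying
#'   fit object.
#' @export
fit_glm <- function(y, X = NULL, offset_log = NULL,
                    family = c("poisson", "negative_binomial")) {
  family <- match.arg(family)
  n <- length(y)
  if (any(y < 0)) stop("counts must be nonnegative")
  if (is.null(offset_log)) offset_log <- rep(0, n)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  M <- cbind(`(Intercept)` = 1, X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[-seq_len(qrM$rank)][1]
    dropped <- setdiff(colnames(M), colnames(M)[qrM$pivot[seq_len(qrM$rank)]])
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  df <- data.frame(.y = y, check.names = FALSE)
  if (ncol(X) > 0L) df <- cbind(df, as.data.frame(X))
  fml <- stats::as.formula(paste(".y ~", if (ncol(X)) paste(sprintf("`%s`", colnames(X)), collapse = " + ") else "1"))
  if (family == "poisson") {
    fit <- stats::glm(fml, data = df, family = stats::poisson(),
                      offset = offset_log, control = list(maxit = 100))
    if (!fit$converged) stop("IRLS did not converge in 100 iterations")
    theta <- NULL
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fit <- suppressWarnings(
      MASS::glm.nb(stats::update.formula(fml, . ~ . + offset(offset_log)),
                   data = cbind(df, offset_log = offset_log),
                   control = stats::glm.control(maxit = 100)))
    if (!fit$converged) stop("NB IRLS/theta alternation did not converge")
    theta <- fit$theta
    ll <- as.numeric(stats::logLik(fit))
  }
  structure(list(family = family,
                 coefficients = stats::coef(fit),
                 covariance = as.matrix(stats::vcov(fit)),
                 dispersion = theta,
                 log_likelihood = ll,
                 fitted_means = as.numeric(stats::fitted(fit)),
                 n = n, k = ncol(M) + (family == "negative_binomial"),
                 offset_log = offset_log,
                 fit = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("glm_fit (", x$family, "), logLik = ", round(x$log_likelihood, 2), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Pearson overdispersion statistic
#'
#' Pearson chi-square divided by residual degrees of freedom, with the
#' variance function of the fitted family (`mu` for Poisson,
#' `mu + mu^2/theta` for negative binomial). Values well above 1 indicate
#' extra-Poisson variation.
#'
#' @param fit a [fit_glm()] result.
#' @param y the observed counts.
#' @return scalar overdispersion statistic.
#' @export
overdispersion_stat <- function(fit, y) {
  mu <- fit$fitted_means
  v <- switch(fit$family,
              poisson = mu,
              negative_binomial = mu + mu^2 / fit$dispersion)
  df_res <- fit$n - length(fit$coefficients)
  sum((y - mu)^2 / v) / df_res
}

#' Pairwise-correlation covariate filter
#'
#' Greedily removes one member of each covariate pair whose absolute Pearson
#' correlation strictly exceeds `threshold`. Within a violating pair the
#' variable with the larger mean absolute correlation against all remaining
#' variables is dropped; ties keep the earlier column.
#'
#' @param X numeric covariate matrix or data frame (no missing cells).
#' @param threshold drop threshold on `|r|` (default 0.6, strict).
#' @return list with `X` (reduced matrix) and `dropped` (data frame of
#'   variable, partner, r).
#' @export
correlation_filter <- function(X, threshold = 0.6) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two covariates")
  if (anyNA(X)) stop("missing cells; impute first")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("constant column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  keep <- colnames(X)
  dropped <- data.frame(variable = character(0), partner = character(0), r = numeric(0))
  repeat {
    R <- stats::cor(X[, keep, drop = FALSE])
    diag(R) <- 0
    if (max(abs(R)) <= threshold) break
    w <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1L, ]
    a <- keep[w[1L]]; b <- keep[w[2L]]
    mean_abs <- function(v) mean(abs(R[v, setdiff(seq_along(keep), w)]))
    victim <- if (length(keep) > 2L && mean_abs(w[2L]) > mean_abs(w[1L])) b
              else if (length(keep) > 2L && mean_abs(w[2L]) < mean_abs(w[1L])) a
              else keep[max(w)]  # tie (or only two left): keep the earlier column
    partner <- if (victim == a) b else a
    dropped <- rbind(dropped, data.frame(variable = victim, partner = partner,
                                         r = R[a, b]))
    keep <- setdiff(keep, victim)
    if (length(keep) < 2L) break
  }
  list(X = X[, keep, drop = FALSE], dropped = dropped)
}

#' Forward stepwise selection by BIC
#'
#' Starting from the intercept-only count GLM, at each step adds the
#' candidate giving the largest BIC decrease (`BIC = -2 logLik + k log n`)
#' and stops when no addition decreases BIC. Candidates that make the design
#' rank deficient are skipped.
#'
#' @param y counts.
#' @param candidates covariate matrix of candidate columns.
#' @param offset_log log offset.
#' @param family GLM family for the selection fits (default Poisson, with
#'   the log-expected-count offset, matching the final mapping model).
#' @return list with `selected` (character vector), `bic_path` (data frame
#'   of variable added and BIC, first row the intercept-only model), and
#'   `fit` for the selected model.
#' @export
forward_bic <- function(y, candidates, offset_log = NULL, family = "poisson") {
  candidates <- as.matrix(candidates)
  n <- length(y)
  bic_of <- function(cols) {
    f <- fit_glm(y, candidates[, cols, drop = FALSE], offset_log, family)
    -2 * f$log_likelihood + f$k * log(n)
  }
  selected <- character(0)
  current <- bic_of(selected)
  path <- data.frame(variable = "(intercept only)", bic = current,
                     stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(colnames(candidates), selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(v) {
      tryCatch(bic_of(c(selected, v)), error = function(e) Inf)
    }, numeric(1))
    if (min(trial) >= current) break
    best <- remaining[which.min(trial)]
    selected <- c(selected, best)
    current <- min(trial)
    path <- rbind(path, data.frame(variable = best, bic = current))
  }
  fit <- fit_glm(y, candidates[, selected, drop = FALSE], offset_log, family)
  list(selected = selected, bic_path = path, fit = fit)
}

#' Variance-inflation-factor filter
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the least-squares regression of column j
#' on all other columns. Columns with VIF above the threshold are removed
#' iteratively, largest first, recomputing VIFs after each removal; exact
#' collinearity yields `VIF = Inf` and is removed first.
#'
#' @param X covariate matrix.
#' @param threshold removal threshold (default 10).
#' @return list with `X` (reduced), `vif` (final VIF table) and
#'   `vif_initial` (VIFs before any removal).
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two covariates")
  vifs <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      fit <- stats::lm.fit(cbind(1, M[, -j, drop = FALSE]), M[, j])
      rss <- sum(fit$residuals^2)
      tss <- sum((M[, j] - mean(M[, j]))^2)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1), USE.NAMES = FALSE)
  }
  keep <- colnames(X)
  v <- vifs(X)
  names(v) <- keep
  initial <- v
  while (length(keep) >= 2L) {
    v <- vifs(X[, keep, drop = FALSE])
    names(v) <- keep
    if (max(v) <= threshold) break
    # largest VIF removed first; among ties (e.g. an exactly collinear set,
    # all Inf) the latest column goes, so derived columns leave before sources
    worst <- max(which(v == max(v)))
    keep <- setdiff(keep, keep[worst])
  }
  list(X = X[, keep, drop = FALSE], vif = v, vif_initial = initial)
}

#' FDR-controlled pairwise interaction scan
#'
#' For every unordered pair of retained covariates, fits the
#' negative-binomial model with both main effects plus their product and
#' collects the Wald p-value of the product term; Benjamini-Hochberg
#' adjustment is applied across all pairs and pairs with adjusted p below
#' `alpha` are flagged for inclusion in the spatial model. Pairs whose fit
#' fails are recorded and excluded from the FDR family with a warning.
#'
#' @param y counts.
#' @param X_retained matrix of the retained covariates.
#' @param offset_log log offset.
#' @param alpha FDR significance level (default 0.05).
#' @return data frame with one row per pair: `var1`, `var2`, `coefficient`,
#'   `p_raw`, `p_adjusted`, `kept`, `error`.
#' @export
interaction_scan <- function(y, X_retained, offset_log = NULL, alpha = 0.05) {
  X_retained <- as.matrix(X_retained)
  nms <- colnames(X_retained)
  if (length(nms) < 2L) stop("need at least two retained covariates")
  pairs <- utils::combn(nms, 2L)
  res <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    coefficient = NA_real_, p_raw = NA_real_,
                    p_adjusted = NA_real_, kept = FALSE,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    M <- cbind(X_retained[, c(a, b), drop = FALSE],
               interaction = X_retained[, a] * X_retained[, b])
    f <- tryCatch(fit_glm(y, M, offset_log, "negative_binomial"),
                  error = function(e) e)
    if (inherits(f, "error")) {
      res$error[k] <- conditionMessage(f)
      next
    }
    est <- f$coefficients[["interaction"]]
    se <- sqrt(f$covariance["interaction", "interaction"])
    res$coefficient[k] <- est
    res$p_raw[k] <- 2 * stats::pnorm(-abs(est / se))
  }
  if (anyNA(res$p_raw)) {
    warning(sum(is.na(res$p_raw)), " pair(s) failed to fit and were excluded from the FDR family")
  }
  ok <- !is.na(res$p_raw)
  res$p_adjusted[ok] <- stats::p.adjust(res$p_raw[ok], method = "BH")
  res$kept <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}

#' Chained-equation imputation of missing covariate cells
#'
#' Missing cells are initialized at their column means, then the columns are
#' cycled: each column with missing values is regressed on all the others
#' using its observed rows and the missing cells are replaced by the
#' predictions, for `n_iterations` sweeps. The regressor is either ordinary
#' least squares or a random forest. A single completed table is returned
#' (the completed data feed the mapping model directly; no multiple-draw
#' pooling).
#'
#' @param X matrix or data frame with `NA` cells.
#' @param n_iterations number of sweeps (default 10).
#' @param regressor `"random_forest"` (default) or `"linear"`.
#' @param seed integer seed (random forests are seeded per column/sweep).
#' @param num_trees forest size (default 100).
#' @return completed numeric matrix.
#' @export
impute_chained <- function(X, n_iterations = 10, regressor = c("random_forest", "linear"),
                           seed = 1L, num_trees = 100) {
  regressor <- match.arg(regressor)
  X <- as.matrix(X)
  miss <- is.na(X)
  if (!any(miss)) return(X)
  if (any(colSums(!miss) == 0)) stop("column(s) entirely missing: ",
                                     paste(colnames(X)[colSums(!miss) == 0], collapse = ", "))
  # mean initialization
  for (j in seq_len(ncol(X))) {
    if (any(miss[, j])) X[miss[, j], j] <- mean(X[!miss[, j], j])
  }
  set.seed(seed)
  for (it in seq_len(n_iterations)) {
    for (j in seq_len(ncol(X))) {
      mj <- miss[, j]
      if (!any(mj)) next
      obs <- !mj
      others <- X[, -j, drop = FALSE]
      if (regressor == "linear") {
        fit <- stats::lm.fit(cbind(1, others[obs, , drop = FALSE]), X[obs, j])
        pred <- drop(cbind(1, others[mj, , drop = FALSE]) %*% fit$coefficients)
      } else {
        df <- data.frame(.target = X[obs, j], others[obs, , drop = FALSE])
        rf <- ranger::ranger(.target ~ ., data = df, num.trees = num_trees,
                             seed = seed + 1000L * it + j, num.threads = 1L)
        pred <- stats::predict(rf, data.frame(others[mj, , drop = FALSE]))$predictions
      }
      X[mj, j] <- pred
    }
  }
  X
}

#' The full covariate-screening funnel
#'
#' Imputation (if needed), pairwise-correlation filter, forward-BIC
#' selection, VIF pruning, and the FDR-controlled interaction scan, in that
#' order, returning a single screening report.
#'
#' @param y counts.
#' @param X candidate covariate matrix (may contain `NA`).
#' @param offset_log log offset.
#' @param corr_threshold pairwise `|r|` drop threshold (default 0.6).
#' @param vif_threshold VIF drop threshold (default 10).
#' @param fdr_alpha FDR level for the interaction scan (default 0.05).
#' @param imputer passed to [impute_chained()] as `regressor`.
#' @param seed integer seed.
#' @return object of class `screening_report`: `X_completed`, `retained`,
#'   `correlation_dropped`, `bic_path`, `vif_table`, `interactions`.
#' @export
screen_covariates <- function(y, X, offset_log = NULL,
                              corr_threshold = 0.6, vif_threshold = 10,
                              fdr_alpha = 0.05, imputer = "random_forest",
                              seed = 1L) {
  X <- as.matrix(X)
  X_completed <- if (anyNA(X)) impute_chained(X, regressor = imputer, seed = seed) else X
  cf <- correlation_filter(X_completed, corr_threshold)
  fb <- forward_bic(y, cf$X, offset_log)
  interactions <- NULL
  if (length(fb$selected) >= 2L) {
    vf <- vif_filter(X_completed[, fb$selected, drop = FALSE], vif_threshold)
    retained <- colnames(vf$X)
    vif_table <- vf$vif
    if (length(retained) >= 2L) {
      interactions <- interaction_scan(y, X_completed[, retained, drop = FALSE],
                                       offset_log, fdr_alpha)
    }
  } else {
    retained <- fb$selected
    vif_table <- if (length(fb$selected)) stats::setNames(rep(1, length(fb$selected)), fb$selected) else numeric(0)
  }
  structure(list(X_completed = X_completed, retained = retained,
                 correlation_dropped = cf$dropped, bic_path = fb$bic_path,
                 vif_table = vif_table, interactions = interactions,
                 settings = list(corr_threshold = corr_threshold,
                                 vif_threshold = vif_threshold,
                                 fdr_alpha = fdr_alpha, imputer = imputer,
                                 seed = seed)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("screening_report: retained", length(x$retained), "covariate(s):",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a screening report to JSON
#'
#' @param report a `screening_report`.
#' @param path output file.
#' @export
write_screening_report <- function(report, path) {
  out <- report[c("retained", "correlation_dropped", "bic_path",
                  "vif_table", "interactions", "settings")]
  out$vif_table <- as.list(out$vif_table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}
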