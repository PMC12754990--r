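#' End-to-end pipeline configuration
#'
#' Exactly one of `simulation` (a [simulation_config]) or `input`
#' (`list(geometry =, attributes =)`) must be supplied. The global seed
#' propagates to every stage.
#'
#' @param simulation a [simulation_config], or `NULL`.
#' @param input list with `geometry` (GeoJSON path) and `attributes` (CSV
#'   path), or `NULL`.
#' @param output_dir directory for the report bundle.
#' @param seed global integer seed.
#' @param corr_threshold,vif_threshold,fdr_alpha screening thresholds.
#' @param imputer `"random_forest"` or `"linear"`.
#' @param grid_points integration-grid resolution for the Poisson variants.
#' @param nb_grid_points resolution (per dimension) of the negative-binomial
#'   comparison fit.
#' @param n_draws posterior draws per fit.
#' @param permutations,alpha,fdr cluster-statistic settings.
#' @param tier_center `"reference_1"` or `"sample_mean"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input = NULL,
                            output_dir = tempfile("aremap_run_"),
                            seed = 1L,
                            corr_threshold = 0.6, vif_threshold = 10,
                            fdr_alpha = 0.05, imputer = "random_forest",
                            grid_points = 9, nb_grid_points = 5,
                            n_draws = 1000L,
                            permutations = 999L, alpha = 0.05, fdr = FALSE,
                            tier_center = "reference_1") {
  if (is.null(simulation) == is.null(input)) {
    stop("exactly one of `simulation` or `input` must be set")
  }
  structure(list(simulation = simulation, input = input,
                 output_dir = output_dir, seed = as.integer(seed),
                 corr_threshold = corr_threshold, vif_threshold = vif_threshold,
                 fdr_alpha = fdr_alpha, imputer = imputer,
                 grid_points = grid_points, nb_grid_points = nb_grid_points,
                 n_draws = as.integer(n_draws),
                 permutations = as.integer(permutations), alpha = alpha,
                 fdr = fdr, tier_center = tier_center),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` block is passed to [simulation_config()].
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    if (!is.null(sim$beta)) sim$beta <- unlist(sim$beta)
    if (!is.null(sim$population_range)) sim$population_range <- unlist(sim$population_range)
    cfg$simulation <- do.call(simulation_config, sim)
  }
  do.call(pipeline_config, cfg)
}

.stage_log <- function(log, stage, t0, ...) {
  msg <- sprintf("[%s] %s (%.2fs)", stage, paste(..., collapse = " "),
                 as.numeric(proc.time()[3] - t0))
  message(msg)
  c(log, msg)
}

#' Run the full disease-mapping pipeline
#'
#' Executes, in order: data generation or ingest, chained-equation
#' imputation, the covariate-screening funnel, expected-count
#' standardization, comparison of the four random-effect variants
#' (GLM/IID/CAR/BYM) under the Poisson likelihood plus a negative-binomial
#' fit of the DIC-best structure with the Pearson overdispersion statistic
#' reported alongside, the final fit (lowest DIC), the IID-vs-BYM
#' spatial-confounding check, global Moran and Gi* on the residuals, LISA on
#' the posterior-mean RR, SD-band tiering, and report assembly. Every stage
#' is logged (to the console and `log.txt`); the report JSON/CSV content is
#' a pure function of the inputs, settings and seed.
#'
#' @param config a [pipeline_config].
#' @return invisible list with the stage outputs (`dataset`, `screening`,
#'   `comparison`, `fit`, `confounding`, `clusters`, `tiers`, `report`,
#'   `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  seed <- config$seed
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      state_path <- file.path(config$output_dir, "partial_state.json")
      jsonlite::write_json(list(failed_stage = stage, error = conditionMessage(e),
                                completed = log),
                           state_path, auto_unbox = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           " (partial state in ", state_path, ")", call. = FALSE)
    })
    log <<- .stage_log(log, stage, t0, "done")
    out
  }

  ds <- run_stage("data", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- seed
      d <- simulate_counts(sim)
      list(graph = d$graph, table = d$table, truth = d$truth, report = d$report)
    } else {
      read_area_dataset(config$input$geometry, config$input$attributes)
    }
  })
  graph <- ds$graph
  tab <- ds$table

  X_complete <- run_stage("impute", {
    if (anyNA(tab$X)) impute_chained(tab$X, regressor = config$imputer, seed = seed)
    else tab$X
  })
  tab$X <- X_complete

  tab$E <- run_stage("expected_counts", expected_counts(tab$y, tab$population))

  screening <- run_stage("screen", {
    screen_covariates(tab$y, tab$X, log(tab$E),
                      corr_threshold = config$corr_threshold,
                      vif_threshold = config$vif_threshold,
                      fdr_alpha = config$fdr_alpha,
                      imputer = config$imputer, seed = seed)
  })
  tab$X <- tab$X[, screening$retained, drop = FALSE]
  tab$missing <- tab$missing[, screening$retained, drop = FALSE]

  comparison <- run_stage("compare", {
    specs <- list(
      glm = model_spec("poisson", "none", grid_points = config$grid_points),
      iid = model_spec("poisson", "iid", grid_points = config$grid_points),
      car = model_spec("poisson", "icar", grid_points = config$grid_points),
      bym = model_spec("poisson", "bym", grid_points = config$grid_points))
    compare_models(tab, graph, specs, n_draws = config$n_draws, seed = seed)
  })
  best_re <- comparison$table$model[which.min(comparison$table$dic)]

  family_check <- run_stage("family", {
    nb_spec <- model_spec("negative_binomial",
                          switch(best_re, glm = "none", iid = "iid",
                                 car = "icar", bym = "bym"),
                          grid_points = config$nb_grid_points,
                          nb_grid_points = config$nb_grid_points)
    nb_fit <- fit_model(tab, graph, nb_spec, n_draws = config$n_draws, seed = seed)
    pois_glm <- fit_glm(tab$y, tab$X, log(tab$E), "poisson")
    nb_glm <- tryCatch(fit_glm(tab$y, tab$X, log(tab$E), "negative_binomial"),
                       error = function(e) NULL)
    list(nb_fit = nb_fit,
         overdispersion = list(
           poisson = overdispersion_stat(pois_glm, tab$y),
           negative_binomial = if (!is.null(nb_glm)) overdispersion_stat(nb_glm, tab$y) else NA_real_))
  })

  fit <- run_stage("fit", {
    poisson_best <- comparison$fits[[best_re]]
    if (!is.null(family_check$nb_fit) && family_check$nb_fit$dic < poisson_best$dic) {
      family_check$nb_fit
    } else poisson_best
  })

  confounding <- run_stage("confounding", {
    f_iid <- comparison$fits[["iid"]]
    f_bym <- comparison$fits[["bym"]]
    if (!is.null(f_iid) && !is.null(f_bym) && ncol(tab$X) > 0L) {
      confounding_check(f_iid, f_bym, tab$X)
    } else NULL
  })

  resid <- residuals(fit)
  names(resid) <- tab$area_ids
  residual_moran <- run_stage("residual_moran", {
    global_moran(resid, to_weights(graph, "row_standardized"),
                 permutations = config$permutations, seed = seed)
  })
  residual_gi <- run_stage("residual_gistar", {
    getis_ord_gistar(resid, to_weights(graph, "self_included_binary"))
  })

  rr <- fit$rr$mean
  names(rr) <- fit$area_ids
  clusters <- run_stage("lisa", {
    local_moran(rr, to_weights(graph, "row_standardized"),
                permutations = config$permutations, alpha = config$alpha,
                fdr = config$fdr, seed = seed)
  })

  tiers <- run_stage("tiers", classify_sd_bands(rr, config$tier_center,
                                                area_ids = fit$area_ids))

  paths <- list(csv = file.path(config$output_dir, "per_area.csv"),
                json = file.path(config$output_dir, "summary.json"),
                geojson = if (!is.null(graph$polygons))
                  file.path(config$output_dir, "areas_report.geojson") else NULL)
  report <- run_stage("report", {
    comp_tab <- comparison$table
    comp_tab$overdispersion_poisson <- family_check$overdispersion$poisson
    comp_tab$overdispersion_nb <- family_check$overdispersion$negative_binomial
    build_report(fit, clusters, tiers, paths,
                 residual_gistar = residual_gi, residual_moran = residual_moran,
                 comparison = comp_tab, polygons = graph$polygons)
  })

  writeLines(log, file.path(config$output_dir, "log.txt"))
  invisible(list(dataset = ds, screening = screening, comparison = comparison,
                 family_check = family_check, fit = fit,
                 confounding = confounding, residual_moran = residual_moran,
                 residual_gistar = residual_gi, clusters = clusters,
                 tiers = tiers, report = report, paths = paths))
}
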