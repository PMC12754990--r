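#' Standard-deviation-band relative-risk classification
#'
#' Expresses each area's posterior mean RR as a deviation from the centre in
#' sample-SD units and bins it into the seven bands with cut points at
#' -2.5, -1.5, -0.5, 0.5, 1.5, 2.5 (left-closed, right-open upward). The
#' intervention tier follows the band: above 1.5 SD is tier 1 (intensive
#' programs), (0.5, 1.5] tier 2 (outreach), (-0.5, 0.5] tier 3 (regular
#' surveillance), and at or below -0.5 SD below-reference. The default
#' centre is the reference risk RR = 1 (the national expectation); centring
#' at the sample mean is available.
#'
#' @param rr positive numeric vector of relative risks (>= 2 areas).
#' @param center `"reference_1"` (default) or `"sample_mean"`.
#' @param area_ids optional ids for the output table.
#' @return object of class `tier_table`: data frame with `rr`, `sd_units`,
#'   `band`, `tier`.
#' @export
classify_sd_bands <- function(rr, center = c("reference_1", "sample_mean"),
                              area_ids = NULL) {
  center <- match.arg(center)
  if (length(rr) < 2L) stop("need at least 2 areas")
  s <- stats::sd(rr)
  if (s == 0) stop("zero spread in rr; SD bands undefined")
  c0 <- if (center == "reference_1") 1 else mean(rr)
  sd_units <- (rr - c0) / s
  cuts <- c(-Inf, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, Inf)
  labels <- c("<-2.5", "-2.5..-1.5", "-1.5..-0.5", "-0.5..0.5",
              "0.5..1.5", "1.5..2.5", ">=2.5")
  band <- cut(sd_units, breaks = cuts, labels = labels, right = FALSE)
  tier <- ifelse(sd_units > 1.5, "1",
                 ifelse(sd_units > 0.5, "2",
                        ifelse(sd_units > -0.5, "3", "below-reference")))
  tab <- data.frame(area_id = if (is.null(area_ids)) seq_along(rr) else area_ids,
                    rr = rr, sd_units = sd_units,
                    band = as.character(band), tier = tier,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, center = center, center_value = c0, scale = s),
            class = "tier_table")
}

#' @export
print.tier_table <- function(x, ...) {
  cat("tier_table (center =", x$center, "):\n")
  print(table(tier = x$table$tier))
  invisible(x)
}

#' Assemble the per-area report bundle
#'
#' Joins the fit, cluster and tier results on area id into one per-area CSV
#' and a JSON summary (fixed-effect RR table, model-comparison table when
#' supplied, global Moran of residuals, tier and cluster-label counts).
#' Optionally appends the per-area values to a GeoJSON for external mapping.
#'
#' @param fit a `posterior_fit`.
#' @param clusters a `cluster_result` from [local_moran()] (LISA on RR).
#' @param tiers a `tier_table`.
#' @param paths named list with `csv` and `json` (and optionally `geojson`)
#'   output paths.
#' @param residual_gistar optional `cluster_result` from [getis_ord_gistar()]
#'   on the residuals.
#' @param residual_moran optional [global_moran()] result on the residuals.
#' @param comparison optional model-comparison table from [compare_models()].
#' @param polygons optional named polygon list for the GeoJSON output.
#' @return list with `per_area` (data frame) and `summary` (list), invisibly
#'   after writing.
#' @export
build_report <- function(fit, clusters, tiers, paths,
                         residual_gistar = NULL, residual_moran = NULL,
                         comparison = NULL, polygons = NULL) {
  ids <- fit$area_ids
  ct <- clusters$table
  tt <- tiers$table
  if (!setequal(ids, ct$area_id) || !setequal(ids, tt$area_id)) {
    offenders <- unique(c(setdiff(ids, ct$area_id), setdiff(ct$area_id, ids),
                          setdiff(ids, tt$area_id), setdiff(tt$area_id, ids)))
    stop("area id mismatch between fit, clusters and tiers: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  per_area <- data.frame(area_id = ids,
                         y = fit$y, E = fit$E,
                         rr_mean = fit$rr$mean, rr_lower = fit$rr$lower,
                         rr_upper = fit$rr$upper,
                         residual = residuals(fit),
                         stringsAsFactors = FALSE)
  if (!is.null(fit$area_effects$b_mean)) per_area$random_effect <- fit$area_effects$b_mean
  if (!is.null(fit$area_effects$u_mean)) per_area$structured <- fit$area_effects$u_mean
  per_area$lisa_statistic <- ct$statistic[match(ids, ct$area_id)]
  per_area$lisa_p <- ct$pseudo_p[match(ids, ct$area_id)]
  per_area$lisa_label <- ct$label[match(ids, ct$area_id)]
  per_area$sd_units <- tt$sd_units[match(ids, tt$area_id)]
  per_area$band <- tt$band[match(ids, tt$area_id)]
  per_area$tier <- tt$tier[match(ids, tt$area_id)]
  if (!is.null(residual_gistar)) {
    gt <- residual_gistar$table
    per_area$gistar_z <- gt$statistic[match(ids, gt$area_id)]
    per_area$gistar_label <- gt$label[match(ids, gt$area_id)]
  }

  fe <- fit$fixed_effects
  fixed_tab <- data.frame(variable = rownames(fe),
                          rr = exp(fe$mean), lower = exp(fe$q025),
                          upper = exp(fe$q975), kld = fe$kld,
                          stringsAsFactors = FALSE)
  label_counts <- as.list(table(per_area$lisa_label))
  tier_counts <- as.list(table(per_area$tier))
  summary <- list(model = list(likelihood = fit$spec$likelihood,
                               random_effect = fit$spec$random_effect,
                               dic = fit$dic, waic = fit$waic),
                  fixed_effects = fixed_tab,
                  hyperparameters = fit$hyper,
                  residual_global_moran = if (!is.null(residual_moran))
                    residual_moran[c("I", "expectation", "pseudo_p")] else NULL,
                  lisa_label_counts = label_counts,
                  tier_counts = tier_counts,
                  comparison = comparison)

  utils::write.csv(per_area, paths$csv, row.names = FALSE)
  jsonlite::write_json(summary, paths$json, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  if (!is.null(paths$geojson) && !is.null(polygons)) {
    props <- split(per_area, per_area$area_id)
    props <- lapply(props, function(r) as.list(r[1, setdiff(names(r), "area_id")]))
    write_geojson(polygons, paths$geojson, properties = props)
  }
  invisible(list(per_area = per_area, summary = summary))
}
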