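#' Pipeline configuration
#'
#' Collects and validates every tunable of the two-period stability pipeline.
#'
#' @param periods list of two (or one) integer year vectors; non-overlapping,
#'   each at least 3 years. Defaults to the 2000-2008 / 2009-2017 split of
#'   high versus low human-activity intensity.
#' @param ndvi_threshold low-NDVI exclusion threshold (default 0.1).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters for NDVI
#'   smoothing.
#' @param min_pixels minimum valid pixels per spatial dataset.
#' @param ndvi_scale `"zscore"` (NDVI anomalies scaled to unit SD, as climate
#'   is) or `"detrend"` (detrended, centred anomalies left on the NDVI scale;
#'   under this choice a noiseless synthetic run returns the generating
#'   coefficients exactly).
#' @param resistance_combiner passed to [resistance_score()].
#' @param sig_level optional p-value level for zeroing non-significant
#'   correlations before the ellipsoid (default `NULL`: keep all).
#' @param rf_trees,rf_seed random-forest hyperparameters.
#' @param seed root seed for the synthetic generator stages.
#' @param n_counties,types_per_county,pixels_per_group,latent_loading,noise_sd
#'   synthetic-landscape/ground-truth parameters used when the pipeline
#'   simulates its own inputs.
#' @param climate_trend_by_period list (one element per period) of named
#'   per-variable trends in units per year, for the synthetic climate.
#' @param livestock_trend_per_period per-period grazing-density trends
#'   (SHU/ha/yr) for the synthetic livestock series.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(periods = list(2000:2008, 2009:2017),
                            ndvi_threshold = 0.1,
                            sg_window = 5, sg_polyorder = 2,
                            min_pixels = 30,
                            ndvi_scale = c("zscore", "detrend"),
                            resistance_combiner = "mean",
                            sig_level = NULL,
                            rf_trees = 500, rf_seed = 1,
                            seed = 1,
                            n_counties = 6, types_per_county = 2,
                            pixels_per_group = 60,
                            latent_loading = 0.4, noise_sd = 0.1,
                            climate_trend_by_period = NULL,
                            livestock_trend_per_period = c(0.01, -0.02)) {
  ndvi_scale <- match.arg(ndvi_scale)
  if (!length(periods)) stop("at least one period required", call. = FALSE)
  for (p in periods)
    if (length(p) < 3) stop("each period needs >= 3 years", call. = FALSE)
  if (length(periods) >= 2 &&
      length(Reduce(intersect, periods)))
    stop("periods must not overlap", call. = FALSE)
  if (ndvi_threshold <= 0 || min_pixels <= 0 || sg_window <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (is.null(climate_trend_by_period))
    climate_trend_by_period <- rep(list(c(temperature = 0.03,
                                          precipitation = 0.5,
                                          radiation = -1)),
                                   length(periods))
  structure(list(periods = periods, ndvi_threshold = ndvi_threshold,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 min_pixels = min_pixels, ndvi_scale = ndvi_scale,
                 resistance_combiner = resistance_combiner,
                 sig_level = sig_level, rf_trees = rf_trees,
                 rf_seed = rf_seed, seed = seed,
                 n_counties = n_counties,
                 types_per_county = types_per_county,
                 pixels_per_group = pixels_per_group,
                 latent_loading = latent_loading, noise_sd = noise_sd,
                 climate_trend_by_period = climate_trend_by_period,
                 livestock_trend_per_period = livestock_trend_per_period),
            class = "pipeline_config")
}

# Deterministic per-stage seed derived from the root seed.
derive_seed <- function(root, k) {
  as.integer((as.double(root) * 1103515245 + k * 12345) %%
               (.Machine$integer.max - 1L)) + 1L
}

#' Simulate a complete two-period study
#'
#' Generates every input of the pipeline with known ground truth: a
#' county x grassland-type landscape, per-period monthly climate with
#' period-specific trends, NDVI driven by the autoregressive climate model
#' with pixel-varying coefficients, and county livestock records with
#' period-specific grazing trends.
#'
#' @param config a [pipeline_config()].
#' @return List of class `study` with `landscape`, `truth`, `periods` (one
#'   `list(climate, ndvi)` per period), `livestock` and `config`.
#' @export
simulate_study <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  root <- config$seed
  landscape <- make_landscape(config$n_counties, config$types_per_county,
                              config$pixels_per_group,
                              seed = derive_seed(root, 1))
  truth <- make_ground_truth(landscape,
                             latent_loading = config$latent_loading,
                             noise_sd = config$noise_sd,
                             seed = derive_seed(root, 2))
  periods <- lapply(seq_along(config$periods), function(k) {
    yrs <- config$periods[[k]]
    climate <- simulate_climate(
      landscape, n_months = 12L * length(yrs),
      start = as.Date(sprintf("%d-01-01", min(yrs))),
      trend = config$climate_trend_by_period[[k]],
      seed = derive_seed(root, 10 + k))
    ndvi <- simulate_ndvi(climate, truth, seed = derive_seed(root, 20 + k))
    list(climate = climate, ndvi = ndvi, years = yrs)
  })
  livestock <- simulate_livestock(
    landscape, years = sort(unlist(config$periods)),
    trend_per_period = config$livestock_trend_per_period,
    periods = config$periods, noise_cv = 0.05,
    seed = derive_seed(root, 30))
  structure(list(landscape = landscape, truth = truth, periods = periods,
                 livestock = livestock, config = config),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study> %d pixels, %d period(s) of %s months\n",
              nrow(x$landscape$pixels), length(x$periods),
              paste(vapply(x$periods,
                           function(p) ncol(p$ndvi$values), numeric(1)),
                    collapse = "/")))
  invisible(x)
}

# Per-unit annual climate trend for one period: annual aggregate per pixel,
# unit mean across pixels, OLS slope over years.
unit_climate_trends <- function(climate, landscape, keep_mask) {
  specs <- list(mat = list(var = "temperature", stat = "mean"),
                ap = list(var = "precipitation", stat = "sum"),
                ar = list(var = "radiation", stat = "sum"))
  px <- landscape$pixels
  out <- NULL
  for (nm in names(specs)) {
    ann <- aggregate_series(climate[[specs[[nm]]$var]], "annual",
                            specs[[nm]]$stat)
    ann <- subset_pixels(ann, keep_mask)
    ids <- px$unit_id[match(ann$pixel_id, px$pixel_id)]
    units <- sort(unique(ids))
    slopes <- vapply(units, function(u) {
      m <- colMeans(ann$values[ids == u, , drop = FALSE])
      linear_trend(m, as.numeric(ann$time))$slope
    }, numeric(1))
    df <- data.frame(unit_id = units, slope = slopes)
    names(df)[2] <- paste0("trend_", nm)
    out <- if (is.null(out)) df else merge(out, df, by = "unit_id")
  }
  out
}

#' Run the full stability pipeline
#'
#' Executes, per period: Savitzky-Golay smoothing of NDVI, low-NDVI pixel
#' filtering (a pixel failing the threshold in any period is excluded from
#' all periods so units stay comparable), detrended z-score anomalies, the
#' per-pixel autoregressive fit, the stability triplet with 0-100
#' normalization over the period's retained pixels, space-for-time grouping,
#' and the per-unit dimensionality table. With two or more periods it then
#' computes between-period deltas of dimensionality and of the
#' climate/grazing trends, bivariate regressions and random-forest
#' attribution. With a single period the delta and attribution stages are
#' skipped with a notice.
#'
#' @param config a [pipeline_config()].
#' @param study optional [simulate_study()] result (or a list with the same
#'   shape built from files); simulated from `config` when `NULL`.
#' @param output_dir optional directory; when given, writes
#'   `stability_pixels.csv`, `ellipsoids.csv`, `delta_dimensionality.csv`,
#'   `attribution.csv` and `manifest.json`.
#' @return List of class `pipeline_result` with `triplets` (per period),
#'   `dimensionality` (per period), `delta`, `trend_deltas`, `attribution`
#'   (`table`, `bivariate`, `forest`), `mask` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(study)) study <- simulate_study(config)
  landscape <- study$landscape

  # smooth NDVI, then a mask consistent across periods
  smoothed <- lapply(study$periods, function(p)
    savitzky_golay_smooth(p$ndvi, config$sg_window, config$sg_polyorder))
  masks <- lapply(smoothed, filter_low_ndvi,
                  threshold = config$ndvi_threshold)
  keep <- Reduce(`&`, masks)
  if (!any(keep)) stop("no pixels survive the NDVI filter", call. = FALSE)

  per_period <- lapply(seq_along(study$periods), function(k) {
    p <- study$periods[[k]]
    ndvi_raw <- subset_pixels(smoothed[[k]], keep)
    anoms <- lapply(p$climate, function(ts)
      zscore_anomalies(subset_pixels(ts, keep)))
    ndvi_an <- if (config$ndvi_scale == "zscore")
      zscore_anomalies(ndvi_raw)
    else {
      dt <- detrend_linear(ndvi_raw)
      dt$residuals
    }
    fit <- fit_ar_climate_model(ndvi_an, anoms$temperature,
                                anoms$precipitation, anoms$radiation)
    trip <- stability_triplet(ndvi_raw, fit,
                              combiner = config$resistance_combiner)
    datasets <- group_space_for_time(trip, landscape,
                                     min_pixels = config$min_pixels)
    dim_tab <- dimensionality_table(datasets, sig_level = config$sig_level)
    dim_tab$period <- k
    trip$period <- k
    list(triplet = trip, dimensionality = dim_tab, fit = fit)
  })

  res <- list(
    triplets = lapply(per_period, `[[`, "triplet"),
    dimensionality = lapply(per_period, `[[`, "dimensionality"),
    fits = lapply(per_period, `[[`, "fit"),
    mask = keep, config = config)

  if (length(study$periods) >= 2) {
    d1 <- per_period[[1]]$dimensionality
    d2 <- per_period[[2]]$dimensionality
    shared <- intersect(d1$unit_id, d2$unit_id)
    dd <- delta_dimensionality(d1[d1$unit_id %in% shared, ],
                               d2[d2$unit_id %in% shared, ])
    ct1 <- unit_climate_trends(study$periods[[1]]$climate, landscape, keep)
    ct2 <- unit_climate_trends(study$periods[[2]]$climate, landscape, keep)
    ctd <- merge(ct1, ct2, by = "unit_id", suffixes = c("_1", "_2"))
    trend_deltas <- data.frame(
      unit_id = ctd$unit_id,
      d_trend_mat = ctd$trend_mat_2 - ctd$trend_mat_1,
      d_trend_ap = ctd$trend_ap_2 - ctd$trend_ap_1,
      d_trend_ar = ctd$trend_ar_2 - ctd$trend_ar_1)
    gz <- grazing_trends(study$livestock, landscape$counties,
                         periods = config$periods)
    px <- landscape$pixels
    unit_county <- unique(px[, c("unit_id", "county_id")])
    trend_deltas <- merge(trend_deltas, unit_county, by = "unit_id")
    trend_deltas <- merge(trend_deltas, gz$delta, by = "county_id")
    names(trend_deltas)[names(trend_deltas) == "d_trend_gi"] <- "d_trend_gi"
    res$delta <- dd
    res$trend_deltas <- trend_deltas
    tab <- assemble_attribution_table(trend_deltas, dd$per_unit)
    attribution <- list(table = tab)
    if (nrow(tab) >= 10)
      attribution$bivariate <- bivariate_relationships(tab)
    else message("attribution: < 10 units, bivariate regressions skipped")
    if (nrow(tab) >= 20)
      attribution$forest <- random_forest_attribution(
        tab, n_trees = config$rf_trees, seed = config$rf_seed)
    else message("attribution: < 20 units, random forest skipped")
    res$attribution <- attribution
  } else {
    message("single period: delta and attribution stages skipped")
  }
  class(res) <- "pipeline_result"
  if (!is.null(output_dir)) write_pipeline_outputs(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d period(s), %d retained pixels\n",
              length(x$triplets), sum(x$mask)))
  for (k in seq_along(x$dimensionality))
    cat(sprintf("  period %d: %d units, mean D = %.3f\n", k,
                nrow(x$dimensionality[[k]]),
                mean(x$dimensionality[[k]]$dimensionality)))
  if (!is.null(x$delta))
    cat(sprintf("  mean delta D = %.4f (%.1f%% of units decreasing)\n",
                x$delta$summary[["mean_delta"]],
                x$delta$summary[["pct_decreasing"]]))
  invisible(x)
}

# Write CSV/JSON pipeline outputs plus a manifest with a config hash.
write_pipeline_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, file) utils::write.csv(
    df, file.path(output_dir, file), row.names = FALSE)
  wr(do.call(rbind, res$triplets), "stability_pixels.csv")
  wr(do.call(rbind, res$dimensionality), "ellipsoids.csv")
  if (!is.null(res$delta)) wr(res$delta$per_unit,
                              "delta_dimensionality.csv")
  if (!is.null(res$attribution)) {
    wr(res$attribution$table, "attribution.csv")
    if (!is.null(res$attribution$forest)) {
      f <- res$attribution$forest
      wr(data.frame(predictor = names(f$importance),
                    pct_inc_mse = unname(f$importance),
                    scaled = unname(f$importance_scaled),
                    r_squared_oob = f$r_squared),
         "attribution_importance.csv")
    }
  }
  cfg <- res$config
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("stabdim")),
    r_version = as.character(getRversion()),
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(tmp)),
    n_pixels_retained = sum(res$mask),
    outputs = list.files(output_dir, pattern = "\\.csv$"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' Write a gridded series to CSV
#'
#' Plain-text wide format: one row per pixel (`pixel_id` first column), one
#' column per time stamp (ISO date or year header).
#'
#' @param series a [grid_ts()].
#' @param path output file path.
#' @export
write_grid_csv <- function(series, path) {
  stopifnot(inherits(series, "grid_ts"))
  df <- data.frame(pixel_id = series$pixel_id, series$values)
  names(df)[-1] <- paste0("t_", format(series$time))
  attrline <- sprintf("# variable=%s units=%s resolution=%s",
                      series$variable, series$units, series$resolution)
  con <- file(path, "w")
  writeLines(attrline, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a gridded series from CSV written by [write_grid_csv()]
#'
#' @param path input file path.
#' @return A [grid_ts()].
#' @export
read_grid_csv <- function(path) {
  header <- readLines(path, n = 1)
  meta <- regmatches(header,
                     gregexpr("(\\w+)=([^ ]+)", header))[[1]]
  kv <- strsplit(meta, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  stamps <- sub("^t_", "", names(df)[-1])
  time <- if (meta[["resolution"]] == "annual") as.integer(stamps)
          else as.Date(stamps)
  grid_ts(unname(as.matrix(df[, -1, drop = FALSE])), time, meta[["variable"]],
          ifelse(meta[["units"]] == "NA", "", meta[["units"]]),
          meta[["resolution"]], pixel_id = df$pixel_id)
}
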