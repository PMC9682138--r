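# Shared fixture builders; everything is generated in code at test time.

# Minimal monthly grid_ts from a pixels x time matrix.
mk_ts <- function(values, variable = "ndvi", units = "",
                  start = as.Date("2000-01-01")) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  grid_ts(values, seq(start, by = "month", length.out = ncol(values)),
          variable, units, "monthly")
}

# Small landscape + climate + truth for pipeline-level tests.
mk_small_study <- function(seed = 1, latent_loading = 0, noise_sd = 0.1,
                           pixels_per_group = 40, n_months = 108) {
  ls <- make_landscape(2, 2, pixels_per_group, seed = seed)
  truth <- make_ground_truth(ls, latent_loading = latent_loading,
                             noise_sd = noise_sd, seed = seed + 1)
  climate <- simulate_climate(ls, n_months, seed = seed + 2)
  ndvi <- simulate_ndvi(climate, truth, seed = seed + 3)
  list(landscape = ls, truth = truth, climate = climate, ndvi = ndvi)
}

# Fit the AR model on the generator's emitted anomaly scale (exact contract).
fit_on_anomaly_scale <- function(ndvi, climate) {
  an <- grid_ts(ndvi$anomaly, ndvi$time, "ndvi_anomaly", "", "monthly",
                pixel_id = ndvi$pixel_id)
  z <- lapply(climate, zscore_anomalies, detrend = FALSE)
  fit_ar_climate_model(an, z$temperature, z$precipitation, z$radiation)
}

# Synthetic attribution table with planted linear driver effects.
mk_attribution_table <- function(n, effects = c(mat = 0, ap = 0, ar = 0,
                                                gi = 0),
                                 noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  tab <- data.frame(unit_id = sprintf("u%03d", seq_len(n)),
                    d_trend_mat = rnorm(n), d_trend_ap = rnorm(n),
                    d_trend_ar = rnorm(n), d_trend_gi = rnorm(n))
  tab$d_dimensionality <- effects[["mat"]] * tab$d_trend_mat +
    effects[["ap"]] * tab$d_trend_ap + effects[["ar"]] * tab$d_trend_ar +
    effects[["gi"]] * tab$d_trend_gi + rnorm(n, 0, noise_sd)
  tab
}
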