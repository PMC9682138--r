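#' Savitzky-Golay smoothing of a gridded series
#'
#' Applies per-pixel least-squares local-polynomial smoothing, the standard
#' noise calibration for satellite vegetation-index series (cloud and
#' atmospheric artifacts appear as short spikes that a local polynomial fit
#' suppresses while preserving the seasonal shape). Endpoints are handled by
#' polynomial fits within the edge windows, so a series that is exactly
#' polynomial of degree `<= polyorder` is reproduced to machine precision.
#'
#' @param series a [grid_ts()].
#' @param window odd window length, `> polyorder`.
#' @param polyorder local polynomial degree.
#' @return A smoothed `grid_ts` of the same shape and units.
#' @export
savitzky_golay_smooth <- function(series, window = 5, polyorder = 2) {
  stopifnot(inherits(series, "grid_ts"))
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window <= polyorder)
    stop("window must exceed polyorder", call. = FALSE)
  if (ncol(series$values) < window)
    stop("series shorter than the smoothing window", call. = FALSE)
  sm <- t(apply(series$values, 1, signal::sgolayfilt,
                p = polyorder, n = window))
  grid_ts(sm, series$time, series$variable, series$units, series$resolution,
          pixel_id = series$pixel_id)
}

#' Mask pixels with low annual NDVI
#'
#' Sparsely vegetated pixels produce noisy vegetation-index series; any pixel
#' whose calendar-year mean NDVI falls below `threshold` in any complete year
#' is excluded. The returned logical mask (`TRUE` = keep) is meant to be
#' applied consistently to every co-registered variable with
#' [subset_pixels()].
#'
#' @param ndvi a monthly or annual NDVI [grid_ts()] covering at least one
#'   complete calendar year.
#' @param threshold exclusion threshold on annual mean NDVI (default 0.1).
#' @return Logical vector along the pixel axis, `TRUE` for retained pixels,
#'   with attribute `annual_means` (pixels x years matrix).
#' @export
filter_low_ndvi <- function(ndvi, threshold = 0.1) {
  stopifnot(inherits(ndvi, "grid_ts"))
  if (!ncol(ndvi$values)) stop("empty series", call. = FALSE)
  yrs <- ts_years(ndvi)
  if (ndvi$resolution == "monthly") {
    full <- names(which(table(yrs) == 12L))
    if (!length(full))
      stop("NDVI series contains no complete calendar year", call. = FALSE)
    am <- vapply(full, function(y)
      rowMeans(ndvi$values[, yrs == as.integer(y), drop = FALSE]),
      numeric(nrow(ndvi$values)))
  } else {
    am <- ndvi$values
    colnames(am) <- as.character(yrs)
  }
  am <- matrix(am, nrow = nrow(ndvi$values),
               dimnames = list(NULL, colnames(am)))
  keep <- apply(am >= threshold, 1, all)
  structure(keep, annual_means = am)
}

#' Linear detrending of a gridded series
#'
#' Removes a per-pixel ordinary-least-squares line fitted against time
#' (expressed in years), the standard step before computing interannual
#' anomalies so that secular change does not inflate variability.
#'
#' @param series a [grid_ts()] with at least 3 time steps.
#' @return List with `residuals` (a `grid_ts`), `slope` (units per year, per
#'   pixel) and `intercept` (per pixel, at the first time step).
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "grid_ts"))
  nt <- ncol(series$values)
  if (nt < 3) stop("insufficient data: need >= 3 time points", call. = FALSE)
  ty <- time_in_years(series)
  X <- cbind(1, ty)
  XtXi <- solve(crossprod(X))
  B <- unname(series$values %*% X %*% XtXi)  # pixels x (intercept, slope)
  fitted <- B %*% t(X)
  res <- grid_ts(series$values - fitted, series$time, series$variable,
                 series$units, series$resolution, pixel_id = series$pixel_id)
  list(residuals = res, slope = B[, 2], intercept = B[, 1])
}

# Time axis in fractional years since the first stamp.
time_in_years <- function(series) {
  if (inherits(series$time, "Date"))
    as.numeric(series$time - series$time[1]) / 365.25
  else as.numeric(series$time - series$time[1])
}

#' Z-score anomalies of a gridded series
#'
#' Optionally detrends, then centres and scales each pixel's series to mean 0
#' and SD 1, storing every transform parameter so the operation is exactly
#' invertible with [inverse_anomalies()].
#'
#' @param series a [grid_ts()].
#' @param detrend remove a per-pixel linear trend first (default `TRUE`).
#' @return An object of classes `anomaly_series` and `grid_ts` with extra
#'   elements `center`, `scale`, `slope`, `intercept`.
#' @export
zscore_anomalies <- function(series, detrend = TRUE) {
  stopifnot(inherits(series, "grid_ts"))
  slope <- intercept <- rep(0, nrow(series$values))
  work <- series
  if (detrend) {
    dt <- detrend_linear(series)
    work <- dt$residuals
    slope <- dt$slope
    intercept <- dt$intercept
  }
  ctr <- rowMeans(work$values)
  scl <- apply(work$values, 1, stats::sd)
  bad <- which(scl == 0)
  if (length(bad))
    stop("degenerate pixel(s) with zero variance: ",
         paste(series$pixel_id[bad], collapse = ", "), call. = FALSE)
  out <- grid_ts((work$values - ctr) / scl, series$time, series$variable,
                 "z-score", series$resolution, pixel_id = series$pixel_id)
  out$center <- ctr
  out$scale <- scl
  out$slope <- slope
  out$intercept <- intercept
  class(out) <- c("anomaly_series", "grid_ts")
  out
}

#' Invert a z-score anomaly transform
#'
#' @param anomaly an [zscore_anomalies()] result.
#' @return The original `grid_ts` (trend restored if one was removed).
#' @export
inverse_anomalies <- function(anomaly) {
  stopifnot(inherits(anomaly, "anomaly_series"))
  vals <- anomaly$values * anomaly$scale + anomaly$center
  ty <- time_in_years(anomaly)
  vals <- vals + cbind(anomaly$intercept, anomaly$slope) %*% t(cbind(1, ty))
  grid_ts(vals, anomaly$time, anomaly$variable, "", anomaly$resolution,
          pixel_id = anomaly$pixel_id)
}

#' Temporal aggregation of a gridded series
#'
#' Aggregates daily series to monthly, or daily/monthly series to annual, by
#' the given statistic. Intensive variables (temperature, NDVI) are
#' conventionally aggregated by `"mean"`, fluxes (precipitation, radiation)
#' by `"sum"`. A partial terminal period (incomplete month or year) is
#' dropped rather than aggregated from partial data.
#'
#' @param series a [grid_ts()] at daily or monthly resolution.
#' @param to target resolution, `"monthly"` or `"annual"`; must be coarser
#'   than the source.
#' @param statistic `"mean"` or `"sum"`.
#' @return An aggregated `grid_ts`.
#' @export
aggregate_series <- function(series, to = c("monthly", "annual"),
                             statistic = c("mean", "sum")) {
  stopifnot(inherits(series, "grid_ts"))
  to <- match.arg(to)
  statistic <- match.arg(statistic)
  lv <- c(daily = 1, monthly = 2, annual = 3)
  if (lv[[to]] <= lv[[series$resolution]])
    stop("target resolution must be coarser than the source", call. = FALSE)
  if (to == "monthly") {
    key <- format(series$time, "%Y-%m")
    expected <- function(k) {
      first <- as.Date(paste0(k, "-01"))
      as.integer(seq(first, by = "month", length.out = 2)[2] - first)
    }
  } else {
    key <- format_year(series$time)
    expected <- function(k)
      if (series$resolution == "monthly") 12L
      else as.integer(as.Date(paste0(as.integer(k) + 1, "-01-01")) -
                        as.Date(paste0(k, "-01-01")))
  }
  counts <- table(key)
  keys <- names(counts)
  # drop incomplete terminal periods (leading or trailing)
  complete <- vapply(keys, function(k) counts[[k]] >= expected(k), logical(1))
  keys <- keys[complete]
  if (!length(keys)) stop("no complete periods to aggregate", call. = FALSE)
  agg <- vapply(keys, function(k) {
    block <- series$values[, key == k, drop = FALSE]
    if (statistic == "mean") rowMeans(block) else rowSums(block)
  }, numeric(nrow(series$values)))
  agg <- matrix(agg, nrow = nrow(series$values))
  newtime <- if (to == "monthly") as.Date(paste0(keys, "-01"))
             else as.integer(keys)
  grid_ts(agg, newtime, series$variable, series$units, to,
          pixel_id = series$pixel_id)
}

format_year <- function(time) {
  if (inherits(time, "Date")) format(time, "%Y") else as.character(time)
}
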