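#' Simulate monthly climate series for a synthetic landscape
#'
#' Generates co-registered monthly temperature, precipitation and radiation
#' grids: each pixel's series is a seasonal harmonic (period 12 months) plus a
#' linear trend plus Gaussian white noise, with a pixel-specific baseline
#' offset so that pixels differ spatially. Precipitation is clipped at zero.
#' Defaults emulate a high-altitude continental grassland climate.
#'
#' @param landscape a [make_landscape()] result.
#' @param n_months series length in months (>= 24).
#' @param start first month (a `Date`, day ignored).
#' @param mean named vector, per-variable climatological mean
#'   (`temperature` degC, `precipitation` mm/mo, `radiation` MJ m-2/mo).
#' @param seasonal_amplitude named vector, per-variable harmonic amplitude.
#' @param noise_sd named vector, per-variable white-noise SD (>= 0).
#' @param trend named vector, per-variable linear trend in units per year.
#' @param pixel_offset_sd named vector, SD of the per-pixel baseline offsets.
#' @param seed integer seed; fully determines the output.
#'
#' @return Named list of three [grid_ts()]: `temperature`, `precipitation`,
#'   `radiation`.
#' @export
simulate_climate <- function(landscape, n_months,
                             start = as.Date("2000-01-01"),
                             mean = c(temperature = 0, precipitation = 40,
                                      radiation = 600),
                             seasonal_amplitude = c(temperature = 12,
                                                    precipitation = 35,
                                                    radiation = 200),
                             noise_sd = c(temperature = 1.2,
                                          precipitation = 15,
                                          radiation = 40),
                             trend = c(temperature = 0, precipitation = 0,
                                       radiation = 0),
                             pixel_offset_sd = c(temperature = 2,
                                                 precipitation = 8,
                                                 radiation = 30),
                             seed = 1) {
  if (n_months < 24)
    stop("n_months must be at least 24 (two full seasonal cycles)",
         call. = FALSE)
  vars <- c("temperature", "precipitation", "radiation")
  mean <- fill_by_var(mean, vars)
  seasonal_amplitude <- fill_by_var(seasonal_amplitude, vars)
  noise_sd <- fill_by_var(noise_sd, vars)
  trend <- fill_by_var(trend, vars)
  pixel_offset_sd <- fill_by_var(pixel_offset_sd, vars)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  np <- nrow(landscape$pixels)
  t_idx <- seq_len(n_months)
  months <- seq(as.Date(format(start, "%Y-%m-01")), by = "month",
                length.out = n_months)
  units <- c(temperature = "degC", precipitation = "mm",
             radiation = "MJ m-2")
  # peak months differ: temperature/radiation peak mid-summer (Jul),
  # precipitation slightly earlier (Jun) as in monsoon-fed grasslands
  phase <- c(temperature = 7, precipitation = 6, radiation = 7)
  mo_num <- as.integer(format(months, "%m"))

  out <- lapply(vars, function(v) {
    offs <- stats::rnorm(np, 0, pixel_offset_sd[[v]])
    seas <- mean[[v]] +
      seasonal_amplitude[[v]] * cos(2 * pi * (mo_num - phase[[v]]) / 12)
    base <- outer(offs, seas, `+`)
    tr <- trend[[v]] * (t_idx - 1) / 12
    vals <- base + matrix(tr, np, n_months, byrow = TRUE)
    if (noise_sd[[v]] > 0)
      vals <- vals + matrix(stats::rnorm(np * n_months, 0, noise_sd[[v]]),
                            np, n_months)
    if (v == "precipitation") vals[vals < 0] <- 0
    grid_ts(vals, months, v, units[[v]], "monthly",
            pixel_id = landscape$pixels$pixel_id)
  })
  names(out) <- vars
  out
}

# Recycle a scalar or fill a partially named vector over variable names.
fill_by_var <- function(x, vars) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(vars))
    stopifnot(length(x) == length(vars))
    names(x) <- vars
    return(x)
  }
  miss <- setdiff(vars, names(x))
  if (length(miss)) stop("missing values for: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x[vars]
}
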