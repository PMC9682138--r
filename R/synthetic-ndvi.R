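#' Ground-truth generating coefficients for the NDVI simulator
#'
#' Draws per-pixel standardized climate sensitivities (alpha: temperature,
#' beta: precipitation, gamma: radiation), a lag-1 autoregressive coefficient
#' (delta) and a residual noise SD. Coefficients are drawn from a one-factor
#' model: a pixel-level latent factor with loading `latent_loading` is shared
#' by all coefficients and by the (log) noise SD, so that the stability
#' components later derived from them are correlated across pixels to a
#' controllable degree. `latent_loading = 0` gives independent coefficients
#' (a high-dimensionality scenario); loadings near 1 couple invariability,
#' resistance and resilience tightly (a low-dimensionality scenario).
#'
#' @param landscape a [make_landscape()] result.
#' @param mean_coef named numeric: mean `alpha`, `beta`, `gamma`, `delta`.
#' @param sd_coef named numeric: between-pixel SD of each coefficient; use 0
#'   for identical coefficients on every pixel.
#' @param latent_loading common-factor loading in `[0, 1]`.
#' @param noise_sd mean residual SD of the NDVI anomaly recursion (>= 0).
#' @param noise_cv between-pixel coefficient of variation of the noise SD
#'   (log-normal spread; 0 gives the same SD everywhere).
#' @param ndvi_mean long-term mean NDVI level added back to anomalies.
#' @param ndvi_seasonal_amplitude amplitude of the mean NDVI seasonal cycle.
#' @param anomaly_scale NDVI units per unit of standardized anomaly.
#' @param trend_per_year per-pixel NDVI linear trend, units NDVI/yr (scalar
#'   or length-n_pixels).
#' @param max_abs_delta deltas are clamped inside (-max_abs_delta,
#'   max_abs_delta) to keep every pixel's recursion stationary.
#' @param seed integer seed.
#'
#' @return An object of class `ground_truth`: list with `coef` (data.frame
#'   pixel_id, alpha, beta, gamma, delta, noise_sd, trend_per_year), the NDVI
#'   profile parameters, `latent_loading` and `seed`.
#' @export
make_ground_truth <- function(landscape,
                              mean_coef = c(alpha = 0.4, beta = 0.3,
                                            gamma = 0.1, delta = 0.3),
                              sd_coef = c(alpha = 0.12, beta = 0.10,
                                          gamma = 0.05, delta = 0.15),
                              latent_loading = 0,
                              noise_sd = 0.1, noise_cv = 0.4,
                              ndvi_mean = 0.45,
                              ndvi_seasonal_amplitude = 0.15,
                              anomaly_scale = 0.08,
                              trend_per_year = 0,
                              max_abs_delta = 0.95,
                              seed = 1) {
  stopifnot(latent_loading >= 0, latent_loading <= 1, noise_sd >= 0,
            noise_cv >= 0, max_abs_delta > 0, max_abs_delta < 1)
  cf <- fill_by_var(mean_coef, c("alpha", "beta", "gamma", "delta"))
  sf <- fill_by_var(sd_coef, c("alpha", "beta", "gamma", "delta"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  np <- nrow(landscape$pixels)
  u <- stats::rnorm(np)                       # shared latent factor
  lam <- latent_loading
  resid_load <- sqrt(1 - lam^2)
  draw <- function(mu, sdv)
    mu + sdv * (lam * u + resid_load * stats::rnorm(np))
  alpha <- draw(cf[["alpha"]], sf[["alpha"]])
  beta  <- draw(cf[["beta"]],  sf[["beta"]])
  gamma <- draw(cf[["gamma"]], sf[["gamma"]])
  delta <- draw(cf[["delta"]], sf[["delta"]])
  delta <- pmin(pmax(delta, -max_abs_delta), max_abs_delta)
  ln_sd <- sqrt(log(1 + noise_cv^2))
  nsd <- if (noise_sd == 0) rep(0, np) else
    noise_sd * exp(ln_sd * (lam * u + resid_load * stats::rnorm(np)) -
                     ln_sd^2 / 2)
  trend <- rep_len(trend_per_year, np)

  structure(list(
    coef = data.frame(pixel_id = landscape$pixels$pixel_id,
                      alpha = alpha, beta = beta, gamma = gamma,
                      delta = delta, noise_sd = nsd,
                      trend_per_year = trend),
    ndvi_mean = ndvi_mean,
    ndvi_seasonal_amplitude = ndvi_seasonal_amplitude,
    anomaly_scale = anomaly_scale,
    latent_loading = latent_loading,
    seed = as.integer(seed)),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d pixels, latent loading %.2f, mean noise_sd %.3f\n",
    nrow(x$coef), x$latent_loading, mean(x$coef$noise_sd)))
  invisible(x)
}

#' Simulate an NDVI grid from climate series and ground truth
#'
#' Runs the linear autoregressive climate-sensitivity model generatively:
#' each climate series is z-scored per pixel, the NDVI anomaly recursion
#' \deqn{x_t = \alpha T_t + \beta P_t + \gamma R_t + \delta x_{t-1} +
#' \epsilon_t} is iterated from \eqn{x_0 = 0} with
#' \eqn{\epsilon_t \sim N(0, \mathrm{noise\_sd}^2)}, and the anomaly is
#' mapped back to NDVI units via a seasonal mean profile, the anomaly scale,
#' and a linear trend, finally clipped to `[0, 1]`.
#'
#' The emitted anomaly matrix (before scaling/clipping) is attached as the
#' `anomaly` element of the result; with `noise_sd = 0` it satisfies the
#' recursion exactly at every time step, which is what makes noiseless
#' coefficient recovery an exact contract.
#'
#' @param climate named list of three aligned [grid_ts()] as produced by
#'   [simulate_climate()].
#' @param truth a [make_ground_truth()] result on the same pixel set.
#' @param seed integer seed for the innovation noise.
#'
#' @return A [grid_ts()] of NDVI in `[0, 1]` with extra element `anomaly`
#'   (pixels x time matrix of standardized NDVI anomalies).
#' @export
simulate_ndvi <- function(climate, truth, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  te <- climate$temperature; pr <- climate$precipitation
  ra <- climate$radiation
  check_aligned(te, pr, "climate series")
  check_aligned(te, ra, "climate series")
  if (!identical(te$pixel_id, truth$coef$pixel_id))
    stop("ground truth and climate pixel axes differ", call. = FALSE)
  if (any(abs(truth$coef$delta) >= 1))
    stop("|delta| >= 1: nonstationary autoregression", call. = FALSE)

  zmat <- function(ts) {
    m <- rowMeans(ts$values)
    s <- apply(ts$values, 1, stats::sd)
    if (any(s == 0)) stop("constant climate series cannot be z-scored",
                          call. = FALSE)
    (ts$values - m) / s
  }
  Tz <- zmat(te); Pz <- zmat(pr); Rz <- zmat(ra)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  cf <- truth$coef
  np <- nrow(cf); nt <- ncol(Tz)
  forcing <- cf$alpha * Tz + cf$beta * Pz + cf$gamma * Rz
  eps <- matrix(0, np, nt)
  if (any(cf$noise_sd > 0))
    eps <- matrix(stats::rnorm(np * nt), np, nt) * cf$noise_sd
  anom <- matrix(0, np, nt)
  anom[, 1] <- forcing[, 1] + eps[, 1]
  for (t in 2:nt)
    anom[, t] <- forcing[, t] + cf$delta * anom[, t - 1] + eps[, t]

  mo <- as.integer(format(te$time, "%m"))
  profile <- truth$ndvi_mean +
    truth$ndvi_seasonal_amplitude * cos(2 * pi * (mo - 7) / 12)
  t_yr <- (seq_len(nt) - 1) / 12
  ndvi <- matrix(profile, np, nt, byrow = TRUE) +
    truth$anomaly_scale * anom +
    outer(cf$trend_per_year, t_yr)
  ndvi[ndvi < 0] <- 0
  ndvi[ndvi > 1] <- 1

  out <- grid_ts(ndvi, te$time, "ndvi", "", "monthly", pixel_id = cf$pixel_id)
  out$anomaly <- anom
  out
}
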