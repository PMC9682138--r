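#' Temporal invariability of vegetation productivity
#'
#' The ratio of a pixel's long-term mean NDVI to its temporal standard
#' deviation, i.e. the inverse coefficient of variation. The SD is taken on
#' linearly detrended residuals so that a secular greening or browning trend
#' does not masquerade as instability, while the mean is taken on the raw
#' series and keeps its physical interpretation.
#'
#' @param ndvi a raw (not anomaly-transformed) NDVI [grid_ts()] with at least
#'   3 time steps.
#' @return Numeric vector of raw invariability per pixel; pixels whose
#'   residual SD is zero are returned as `NA` (undefined, to be excluded)
#'   rather than infinity.
#' @export
temporal_invariability <- function(ndvi) {
  stopifnot(inherits(ndvi, "grid_ts"))
  dt <- detrend_linear(ndvi)
  m <- rowMeans(ndvi$values)
  s <- apply(dt$residuals$values, 1, stats::sd)
  # residual SD at rounding-noise level counts as zero (constant series)
  degenerate <- s <= 1e-10 * pmax(1, abs(m))
  out <- ifelse(!degenerate, m / s, NA_real_)
  names(out) <- ndvi$pixel_id
  out
}

#' Fit the autoregressive climate-sensitivity model per pixel
#'
#' Ordinary least squares of the NDVI anomaly on the contemporaneous
#' temperature, precipitation and radiation anomalies and its own lag-1
#' value:
#' \deqn{NDVI_t = \alpha T_t + \beta P_t + \gamma R_t + \delta NDVI_{t-1} +
#' \epsilon_t.}
#' The standardized sensitivities \eqn{\alpha, \beta, \gamma} measure
#' resistance to temperature, drought and radiation perturbation; the lag-1
#' coefficient \eqn{\delta} measures the memory of the system, hence
#' resilience (a larger \eqn{|\delta|} means slower return to the mean). No
#' intercept is fitted by default because every input is a centred anomaly.
#' The first time step is dropped by the lag.
#'
#' @param ndvi,temp,precip,rad aligned anomaly [grid_ts()] objects (e.g. from
#'   [zscore_anomalies()]); `ndvi` may also be a plain `grid_ts` of anomalies.
#' @param intercept include an intercept column (default `FALSE`).
#' @param min_obs minimum usable observations after lagging (default 12).
#' @param condition_threshold design matrices with 2-norm condition number
#'   above this are flagged as collinear and their coefficients set to `NA`.
#' @return An object of class `ar_fit`: data.frame with `pixel_id`, `alpha`,
#'   `beta`, `gamma`, `delta`, their standard errors (`se_*`),
#'   `residual_variance`, `n_obs` and logical `flagged`.
#' @export
fit_ar_climate_model <- function(ndvi, temp, precip, rad,
                                 intercept = FALSE, min_obs = 12,
                                 condition_threshold = 1e8) {
  for (s in list(temp, precip, rad)) check_aligned(ndvi, s)
  nt <- ncol(ndvi$values)
  if (nt - 1L < min_obs)
    stop("insufficient data: ", nt - 1L,
         " usable observations after lagging; need >= ", min_obs,
         call. = FALSE)
  np <- nrow(ndvi$values)
  cur <- 2:nt
  k <- 4L + intercept
  est <- matrix(NA_real_, np, k)
  se <- matrix(NA_real_, np, k)
  sig2 <- rep(NA_real_, np)
  flagged <- rep(FALSE, np)
  for (i in seq_len(np)) {
    X <- cbind(temp$values[i, cur], precip$values[i, cur],
               rad$values[i, cur], ndvi$values[i, cur - 1L])
    if (intercept) X <- cbind(X, 1)
    y <- ndvi$values[i, cur]
    if (kappa(X, exact = FALSE) > condition_threshold) {
      flagged[i] <- TRUE
      next
    }
    fit <- stats::lm.fit(X, y)
    est[i, ] <- fit$coefficients
    dof <- length(y) - fit$rank
    s2 <- sum(fit$residuals^2) / dof
    sig2[i] <- s2
    R <- qr.R(fit$qr)
    XtXi <- chol2inv(R)
    se[i, ] <- sqrt(diag(XtXi) * s2)
  }
  out <- data.frame(pixel_id = ndvi$pixel_id,
                    alpha = est[, 1], beta = est[, 2], gamma = est[, 3],
                    delta = est[, 4],
                    se_alpha = se[, 1], se_beta = se[, 2],
                    se_gamma = se[, 3], se_delta = se[, 4],
                    residual_variance = sig2,
                    n_obs = nt - 1L, flagged = flagged)
  class(out) <- c("ar_fit", "data.frame")
  out
}

#' Composite climate resistance from an autoregressive fit
#'
#' A pixel is resistant when its productivity anomalies respond weakly to
#' climate anomalies, i.e. when the absolute standardized sensitivities are
#' small. The default combiner is the negative equal-weight mean of
#' \eqn{|\alpha|, |\beta|, |\gamma|}, so higher values mean more resistant
#' and a completely insensitive pixel scores 0, the maximum.
#'
#' @param fit an [fit_ar_climate_model()] result.
#' @param combiner `"mean"` (default), `"max"` (negative largest absolute
#'   sensitivity), or `"per_variable"` to return the three negative absolute
#'   sensitivities as a matrix.
#' @return Numeric vector of raw resistance per pixel (or a 3-column matrix
#'   for `"per_variable"`); flagged fits propagate `NA`.
#' @export
resistance_score <- function(fit, combiner = c("mean", "max",
                                               "per_variable")) {
  stopifnot(inherits(fit, "ar_fit"))
  combiner <- match.arg(combiner)
  A <- abs(cbind(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma))
  out <- switch(combiner,
                mean = -rowMeans(A),
                max = -apply(A, 1, max),
                per_variable = -A)
  if (is.matrix(out)) rownames(out) <- fit$pixel_id
  else names(out) <- fit$pixel_id
  out
}

#' Resilience from an autoregressive fit
#'
#' The lag-1 coefficient \eqn{\delta} measures how strongly the current
#' anomaly resembles the previous one; a higher absolute value means a slower
#' return to the mean state, i.e. lower resilience. Raw resilience is
#' therefore \eqn{-|\delta|}: 0 for instant recovery, more negative for
#' longer memory, symmetric in the sign of \eqn{\delta}.
#'
#' @param fit an [fit_ar_climate_model()] result.
#' @return Numeric vector of raw resilience per pixel; flagged fits are `NA`.
#' @export
resilience_score <- function(fit) {
  stopifnot(inherits(fit, "ar_fit"))
  out <- -abs(fit$delta)
  names(out) <- fit$pixel_id
  out
}

#' Min-max normalization to the 0-100 scale
#'
#' Linear rescaling so that the minimum finite value maps to 0 and the
#' maximum to 100; missing values stay missing and ordering is preserved.
#'
#' @param values numeric vector of raw metric values over one normalization
#'   domain (conventionally all retained pixels of one period).
#' @return Numeric vector in `[0, 100]`.
#' @export
normalize_0_100 <- function(values) {
  fin <- values[is.finite(values)]
  if (length(fin) < 2)
    stop("need at least 2 finite values to normalize", call. = FALSE)
  rng <- range(fin)
  if (rng[1] == rng[2])
    stop("degenerate normalization: all values identical", call. = FALSE)
  100 * (values - rng[1]) / (rng[2] - rng[1])
}

#' Per-pixel stability triplet for one period
#'
#' Convenience wrapper computing raw and 0-100 normalized temporal
#' invariability, resistance and resilience for a set of pixels. Raw
#' resilience is \eqn{-|\delta|}, so after normalization higher values mean
#' higher resilience; likewise for resistance.
#'
#' @param ndvi_raw raw NDVI [grid_ts()] for the period (mean/SD of this
#'   series define invariability).
#' @param fit an [fit_ar_climate_model()] result on the same pixels.
#' @param combiner resistance combiner passed to [resistance_score()].
#' @return data.frame with `pixel_id`, `*_raw` columns and normalized
#'   `invariability`, `resistance`, `resilience` in `[0, 100]`.
#' @export
stability_triplet <- function(ndvi_raw, fit, combiner = "mean") {
  stopifnot(inherits(ndvi_raw, "grid_ts"), inherits(fit, "ar_fit"))
  if (!identical(ndvi_raw$pixel_id, fit$pixel_id))
    stop("pixel axes of NDVI series and fit differ", call. = FALSE)
  inv <- temporal_invariability(ndvi_raw)
  rst <- resistance_score(fit, combiner = combiner)
  rsl <- resilience_score(fit)
  data.frame(pixel_id = fit$pixel_id,
             invariability_raw = unname(inv),
             resistance_raw = unname(rst),
             resilience_raw = unname(rsl),
             invariability = normalize_0_100(unname(inv)),
             resistance = normalize_0_100(unname(rst)),
             resilience = normalize_0_100(unname(rsl)))
}
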