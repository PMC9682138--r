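#' Extraterrestrial radiation (FAO-56)
#'
#' Daily extraterrestrial radiation Ra from latitude and day of year, using
#' the FAO-56 formulation: inverse relative Earth-Sun distance, solar
#' declination and sunset hour angle.
#'
#' @param latitude degrees, must satisfy `|latitude| < 66.5` (no polar
#'   day/night handling).
#' @param doy day of year, 1-366.
#' @return Ra in MJ m-2 day-1.
#' @export
fao_extraterrestrial_radiation <- function(latitude, doy) {
  check_fao_latitude(latitude)
  gsc <- 0.0820                                    # MJ m-2 min-1
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
}

#' Daylight hours (FAO-56)
#'
#' @inheritParams fao_extraterrestrial_radiation
#' @return Maximum possible sunshine duration N in hours.
#' @export
fao_daylight_hours <- function(latitude, doy) {
  check_fao_latitude(latitude)
  phi <- latitude * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  24 / pi * ws
}

#' Solar radiation from sunshine hours (FAO-56 Angstrom-Prescott)
#'
#' Converts measured daily sunshine duration to incoming solar radiation:
#' \deqn{R_s = (a_s + b_s \, n/N) \, R_a} where \eqn{R_a} is extraterrestrial
#' radiation and \eqn{N} the daylight duration, both from latitude and day of
#' year. The defaults \eqn{a_s = 0.25}, \eqn{b_s = 0.50} are the FAO-56
#' recommendation where no local calibration exists.
#'
#' @param sunshine_hours measured bright-sunshine duration n, hours (vector).
#' @param latitude station latitude in degrees, `|latitude| < 66.5`.
#' @param doy day of year matching `sunshine_hours` (recycled if scalar).
#' @param a_s Angstrom regression intercept (fraction of Ra on overcast days).
#' @param b_s Angstrom regression slope.
#' @return Solar radiation Rs in MJ m-2 day-1.
#' @export
#' @examples
#' # clear-sky day at 30 N near solstice
#' fao_radiation_from_sunshine(13.9, 30, 172)
fao_radiation_from_sunshine <- function(sunshine_hours, latitude, doy,
                                        a_s = 0.25, b_s = 0.50) {
  check_fao_latitude(latitude)
  if (any(sunshine_hours < 0))
    stop("sunshine hours must be non-negative", call. = FALSE)
  n_len <- max(length(sunshine_hours), length(doy))
  sunshine_hours <- rep_len(sunshine_hours, n_len)
  doy <- rep_len(doy, n_len)
  N <- fao_daylight_hours(latitude, doy)
  if (any(sunshine_hours > N + 1e-9))
    stop("invalid sunshine duration: n exceeds daylight hours N",
         call. = FALSE)
  ra <- fao_extraterrestrial_radiation(latitude, doy)
  (a_s + b_s * sunshine_hours / N) * ra
}

check_fao_latitude <- function(latitude) {
  if (any(abs(latitude) >= 66.5))
    stop("unsupported latitude: |latitude| must be < 66.5 degrees",
         call. = FALSE)
  invisible(TRUE)
}
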