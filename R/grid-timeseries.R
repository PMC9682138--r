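#' Gridded time series container
#'
#' A `grid_ts` holds one variable observed on a fixed set of pixels at a
#' strictly increasing sequence of time stamps: a numeric matrix with one row
#' per pixel and one column per time step, plus the time axis, variable name,
#' units and temporal resolution. All preprocessing and model-fitting
#' functions in the package consume and produce this container.
#'
#' @param values numeric matrix, pixels in rows, time steps in columns.
#' @param time vector of class `Date` (daily/monthly resolution) or integer
#'   years (annual resolution); strictly increasing, no duplicates, length
#'   equal to `ncol(values)`.
#' @param variable variable name, e.g. `"ndvi"`, `"temperature"`.
#' @param units measurement units, e.g. `""` (NDVI), `"degC"`, `"mm"`,
#'   `"MJ m-2"`, `"hours"`.
#' @param resolution one of `"daily"`, `"monthly"`, `"annual"`.
#' @param pixel_id integer pixel identifiers (default `1:nrow(values)`).
#'
#' @return An object of class `grid_ts`.
#' @export
#' @examples
#' ts <- grid_ts(matrix(rnorm(24), 2), seq(as.Date("2000-01-01"),
#'               by = "month", length.out = 12), "ndvi", "", "monthly")
#' dim(ts)
grid_ts <- function(values, time, variable, units = "",
                    resolution = c("monthly", "daily", "annual"),
                    pixel_id = NULL) {
  resolution <- match.arg(resolution)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  storage.mode(values) <- "double"
  if (length(time) != ncol(values))
    stop("length(time) [", length(time), "] must equal ncol(values) [",
         ncol(values), "]", call. = FALSE)
  tn <- as.numeric(time)
  if (anyDuplicated(tn)) stop("duplicate time stamps", call. = FALSE)
  if (is.unsorted(tn, strictly = TRUE))
    stop("time axis must be strictly increasing", call. = FALSE)
  if (is.null(pixel_id)) pixel_id <- seq_len(nrow(values))
  if (length(pixel_id) != nrow(values))
    stop("pixel_id length must match nrow(values)", call. = FALSE)
  structure(
    list(values = values, time = time, variable = as.character(variable),
         units = as.character(units), resolution = resolution,
         pixel_id = as.integer(pixel_id)),
    class = "grid_ts")
}

#' @export
dim.grid_ts <- function(x) dim(x$values)

#' @export
print.grid_ts <- function(x, ...) {
  cat(sprintf("<grid_ts> %s [%s], %d pixels x %d %s steps (%s .. %s)\n",
              x$variable, x$units, nrow(x$values), ncol(x$values),
              x$resolution, format(x$time[1]),
              format(x$time[length(x$time)])))
  invisible(x)
}

#' Subset a gridded series by pixel
#'
#' @param x a [grid_ts()].
#' @param pixels logical mask or integer positions along the pixel axis.
#' @return A `grid_ts` restricted to the selected pixels.
#' @export
subset_pixels <- function(x, pixels) {
  stopifnot(inherits(x, "grid_ts"))
  grid_ts(x$values[pixels, , drop = FALSE], x$time, x$variable, x$units,
          x$resolution, pixel_id = x$pixel_id[pixels])
}

# Stop unless two series share pixel and time axes.
check_aligned <- function(a, b, what = "series") {
  if (!identical(a$pixel_id, b$pixel_id) ||
      !identical(as.numeric(a$time), as.numeric(b$time)))
    stop("misaligned ", what, ": pixel and time axes must match exactly",
         call. = FALSE)
  invisible(TRUE)
}

# Calendar years of a grid_ts time axis.
ts_years <- function(x) {
  if (inherits(x$time, "Date")) as.integer(format(x$time, "%Y"))
  else as.integer(x$time)
}

#' Restrict a gridded series to a span of calendar years
#'
#' @param x a [grid_ts()].
#' @param years integer vector of calendar years to keep.
#' @return A `grid_ts` containing only time steps falling in `years`.
#' @export
window_years <- function(x, years) {
  keep <- ts_years(x) %in% years
  if (!any(keep)) stop("no time steps fall in the requested years",
                       call. = FALSE)
  grid_ts(x$values[, keep, drop = FALSE], x$time[keep], x$variable, x$units,
          x$resolution, pixel_id = x$pixel_id)
}
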