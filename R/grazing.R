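#' Convert livestock head counts to standard sheep units
#'
#' Livestock pressure is expressed in a common currency: one sheep or goat
#' equals one standard sheep unit (SHU); one yak, donkey or horse equals four
#' SHUs. Species columns absent from the input are treated as zero with a
#' warning.
#'
#' @param counts a named numeric vector or data.frame with (a subset of)
#'   columns `sheep`, `goat`, `yak`, `donkey`, `horse`; non-negative counts.
#' @return Numeric SHU total (one value per row for data.frame input).
#' @export
#' @examples
#' to_sheep_units(c(sheep = 100, goat = 50, yak = 20, donkey = 0, horse = 5))
to_sheep_units <- function(counts) {
  if (is.data.frame(counts)) {
    present <- intersect(names(SHU_WEIGHTS), names(counts))
    missing <- setdiff(names(SHU_WEIGHTS), present)
    if (length(missing))
      warning("species column(s) treated as 0: ",
              paste(missing, collapse = ", "), call. = FALSE)
    m <- as.matrix(counts[, present, drop = FALSE])
    if (any(m < 0)) stop("invalid record: negative head count",
                         call. = FALSE)
    return(as.numeric(m %*% SHU_WEIGHTS[present]))
  }
  counts <- unlist(counts)
  present <- intersect(names(SHU_WEIGHTS), names(counts))
  if (!length(present))
    stop("counts must be named by species (sheep, goat, yak, donkey, horse)",
         call. = FALSE)
  missing <- setdiff(names(SHU_WEIGHTS), present)
  if (length(missing))
    warning("species treated as 0: ", paste(missing, collapse = ", "),
            call. = FALSE)
  if (any(counts[present] < 0))
    stop("invalid record: negative head count", call. = FALSE)
  sum(counts[present] * SHU_WEIGHTS[present])
}

#' Grazing intensity
#'
#' The ratio of livestock pressure (in standard sheep units) to the available
#' natural grassland area of the county.
#'
#' @param shu sheep units (non-negative).
#' @param area_ha grassland area in hectares (strictly positive).
#' @return GI in SHU per hectare.
#' @export
grazing_intensity <- function(shu, area_ha) {
  if (any(area_ha <= 0)) stop("invalid area: must be > 0", call. = FALSE)
  shu / area_ha
}

#' Ordinary-least-squares slope of an annual series
#'
#' @param annual_values numeric values, one per year.
#' @param years calendar years (default consecutive).
#' @return Named list with `slope` (units per year), `se` and `intercept`.
#' @export
linear_trend <- function(annual_values,
                         years = seq_along(annual_values)) {
  ok <- is.finite(annual_values) & is.finite(years)
  if (sum(ok) < 3)
    stop("insufficient data: need >= 3 years", call. = FALSE)
  y <- annual_values[ok]; x <- years[ok]
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (length(y) - 2) / sum(xc^2))
  list(slope = slope, se = se, intercept = intercept)
}

#' Per-county grazing-intensity series and per-period trends
#'
#' Converts county-year livestock records to SHU, divides by county grassland
#' area to obtain GI, and fits an OLS trend within each period. Livestock
#' records are county-level: every grassland type within a county inherits
#' the county's GI.
#'
#' @param livestock data.frame with `county_id`, `year` and species count
#'   columns (see [to_sheep_units()]).
#' @param counties data.frame with `county_id`, `area_ha`.
#' @param periods list of integer year vectors (default the two study
#'   periods 2000-2008 and 2009-2017).
#' @return List with `gi` (data.frame county_id, year, shu, gi) and `trends`
#'   (data.frame county_id, period, trend_gi) plus `delta` (data.frame
#'   county_id, d_trend_gi = period 2 minus period 1) when two or more
#'   periods are given.
#' @export
grazing_trends <- function(livestock, counties,
                           periods = list(2000:2008, 2009:2017)) {
  stopifnot(all(c("county_id", "year") %in% names(livestock)))
  shu <- to_sheep_units(livestock[, setdiff(names(livestock),
                                            c("county_id", "year")),
                                  drop = FALSE])
  gi_df <- data.frame(county_id = livestock$county_id,
                      year = livestock$year, shu = shu)
  gi_df <- merge(gi_df, counties[, c("county_id", "area_ha")],
                 by = "county_id", sort = TRUE)
  gi_df$gi <- grazing_intensity(gi_df$shu, gi_df$area_ha)
  gi_df <- gi_df[order(gi_df$county_id, gi_df$year),
                 c("county_id", "year", "shu", "gi")]

  trends <- do.call(rbind, lapply(seq_along(periods), function(k) {
    yrs <- periods[[k]]
    sub <- gi_df[gi_df$year %in% yrs, ]
    do.call(rbind, lapply(split(sub, sub$county_id), function(d)
      data.frame(county_id = d$county_id[1], period = k,
                 trend_gi = linear_trend(d$gi, d$year)$slope)))
  }))
  rownames(trends) <- NULL
  out <- list(gi = gi_df, trends = trends)
  if (length(periods) >= 2) {
    t1 <- trends[trends$period == 1, ]
    t2 <- trends[trends$period == 2, ]
    d <- merge(t1, t2, by = "county_id", suffixes = c("_1", "_2"))
    out$delta <- data.frame(county_id = d$county_id,
                            d_trend_gi = d$trend_gi_2 - d$trend_gi_1)
  }
  out
}
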