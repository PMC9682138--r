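#' Species mix used by the livestock simulator (shares of total sheep units)
#' @keywords internal
SPECIES_SHU_SHARE <- c(sheep = 0.50, goat = 0.25, yak = 0.20,
                       donkey = 0.01, horse = 0.04)

#' Per-head sheep-unit weights
#'
#' One sheep or goat counts as one standard sheep unit (SHU); one yak,
#' donkey or horse counts as four.
#' @export
SHU_WEIGHTS <- c(sheep = 1, goat = 1, yak = 4, donkey = 4, horse = 4)

#' Simulate county-level annual livestock records
#'
#' Emits yearbook-style annual head counts per county for five species
#' (sheep, goat, yak, donkey, horse). Each county follows a declared
#' sheep-unit density trajectory: a county-specific baseline around
#' `base_shu_density`, plus a linear trend per period (so that, e.g., grazing
#' pressure can decline only in the second period), plus optional
#' multiplicative noise. Total SHU = density x county area is split among
#' species with fixed shares and converted to integer head counts.
#'
#' @param landscape a [make_landscape()] result (provides county areas).
#' @param years increasing integer vector of calendar years.
#' @param base_shu_density baseline grazing intensity, SHU per hectare (>= 0).
#' @param trend_per_period numeric vector of density trends (SHU/ha/yr), one
#'   per period in `periods`, recycled if shorter.
#' @param periods list of integer year vectors partitioning `years`; each
#'   period's trend accumulates from that period's first year onward.
#' @param county_cv between-county coefficient of variation of the baseline.
#' @param noise_cv year-to-year multiplicative noise CV (0 = none).
#' @param seed integer seed.
#'
#' @return data.frame with columns `county_id`, `year`, `sheep`, `goat`,
#'   `yak`, `donkey`, `horse` (non-negative integer counts).
#' @export
simulate_livestock <- function(landscape, years,
                               base_shu_density = 0.8,
                               trend_per_period = 0,
                               periods = list(2000:2008, 2009:2017),
                               county_cv = 0.3, noise_cv = 0,
                               seed = 1) {
  if (!length(years) || is.unsorted(years, strictly = TRUE))
    stop("years must be non-empty and strictly increasing", call. = FALSE)
  if (base_shu_density < 0)
    stop("base_shu_density must be non-negative", call. = FALSE)
  trend_per_period <- rep_len(trend_per_period, length(periods))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  cty <- landscape$counties
  base_c <- base_shu_density *
    exp(stats::rnorm(nrow(cty), 0, county_cv) - county_cv^2 / 2)

  # cumulative density offset at each year from per-period trends
  dens_offset <- vapply(years, function(y) {
    off <- 0
    for (k in seq_along(periods)) {
      p <- periods[[k]]
      if (y < min(p)) next
      off <- off + trend_per_period[k] * (min(y, max(p)) - min(p))
    }
    off
  }, numeric(1))

  rows <- vector("list", nrow(cty))
  for (i in seq_len(nrow(cty))) {
    dens <- pmax(base_c[i] + dens_offset, 0)
    if (noise_cv > 0)
      dens <- dens * exp(stats::rnorm(length(years), 0, noise_cv) -
                           noise_cv^2 / 2)
    shu_total <- dens * cty$area_ha[i]
    heads <- vapply(names(SPECIES_SHU_SHARE), function(sp)
      round(shu_total * SPECIES_SHU_SHARE[[sp]] / SHU_WEIGHTS[[sp]]),
      numeric(length(years)))
    if (length(years) == 1L) heads <- matrix(heads, nrow = 1L,
                                             dimnames = list(NULL,
                                               names(SPECIES_SHU_SHARE)))
    rows[[i]] <- data.frame(county_id = cty$county_id[i], year = years,
                            heads, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out[order(out$county_id, out$year), , drop = FALSE]
}
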