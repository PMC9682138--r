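#' Grassland types recognised by the synthetic landscape generator
#' @export
GRASSLAND_TYPES <- c("alpine_meadow", "alpine_steppe", "desert_steppe")

#' Generate a synthetic county-by-grassland-type landscape
#'
#' Builds a mosaic of pixels organised into counties, each county holding one
#' to three grassland types (alpine meadow, alpine steppe, desert steppe).
#' Every county x type combination ("group", the later space-for-time unit)
#' receives `pixels_per_group` pixels. County grassland areas are drawn from a
#' log-normal distribution so that grazing intensities vary realistically
#' across counties. Optionally a fraction of groups is dropped at random,
#' emulating counties that do not contain every grassland type.
#'
#' @param n_counties number of counties (>= 1).
#' @param types_per_county grassland types per county, between 1 and 3.
#' @param pixels_per_group pixels in each county x type group (>= 1).
#' @param seed integer seed; fully determines the landscape.
#' @param dropout probability in `[0, 1)` of dropping any given group (at
#'   least one group per county is always retained).
#' @param mean_area_ha mean county grassland area in hectares.
#'
#' @return An object of class `landscape`: a list with
#'   \describe{
#'     \item{pixels}{data.frame with `pixel_id`, `county_id`,
#'       `grassland_type`, `unit_id` (county x type label).}
#'     \item{counties}{data.frame with `county_id`, `area_ha`.}
#'     \item{seed}{the generating seed.}
#'   }
#' @export
#' @examples
#' ls <- make_landscape(3, 2, 10, seed = 1)
#' nrow(ls$pixels)             # 60
#' length(unique(ls$pixels$unit_id))  # 6
make_landscape <- function(n_counties, types_per_county, pixels_per_group,
                           seed, dropout = 0, mean_area_ha = 2e5) {
  if (n_counties < 1 || types_per_county < 1 || pixels_per_group < 1)
    stop("n_counties, types_per_county and pixels_per_group must be >= 1",
         call. = FALSE)
  if (types_per_county > length(GRASSLAND_TYPES))
    stop("types_per_county cannot exceed ", length(GRASSLAND_TYPES),
         call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must be in [0, 1)", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  groups <- do.call(rbind, lapply(seq_len(n_counties), function(cid) {
    types <- sample(GRASSLAND_TYPES, types_per_county)
    data.frame(county_id = cid, grassland_type = types,
               stringsAsFactors = FALSE)
  }))
  if (dropout > 0) {
    keep <- stats::runif(nrow(groups)) >= dropout
    # never orphan a county: force-keep one random group per fully-dropped one
    for (cid in unique(groups$county_id)) {
      idx <- which(groups$county_id == cid)
      if (!any(keep[idx])) keep[sample(idx, 1L)] <- TRUE
    }
    groups <- groups[keep, , drop = FALSE]
  }
  groups <- groups[order(groups$county_id, groups$grassland_type), ,
                   drop = FALSE]

  pixels <- groups[rep(seq_len(nrow(groups)), each = pixels_per_group), ,
                   drop = FALSE]
  pixels$pixel_id <- seq_len(nrow(pixels))
  pixels$unit_id <- paste(pixels$county_id, pixels$grassland_type, sep = ":")
  rownames(pixels) <- NULL
  pixels <- pixels[, c("pixel_id", "county_id", "grassland_type", "unit_id")]

  counties <- data.frame(
    county_id = seq_len(n_counties),
    area_ha = stats::rlnorm(n_counties, log(mean_area_ha), 0.4))

  structure(list(pixels = pixels, counties = counties,
                 seed = as.integer(seed)),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d pixels, %d counties, %d county x type groups\n",
              nrow(x$pixels), nrow(x$counties),
              length(unique(x$pixels$unit_id))))
  invisible(x)
}

#' Number of county x grassland-type groups in a landscape
#' @param landscape a [make_landscape()] result.
#' @return integer group count.
#' @export
n_groups <- function(landscape) length(unique(landscape$pixels$unit_id))

# Save/restore global RNG state so generators do not disturb the caller.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
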