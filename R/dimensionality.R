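#' Group pixels into space-for-time spatial datasets
#'
#' Stability components are estimated per pixel from a single short series,
#' so their relationships cannot be estimated temporally; instead, variation
#' across the pixels of one county x grassland-type unit substitutes for
#' variation over time. This function splits the per-pixel stability triplets
#' into such units, dropping units with fewer than `min_pixels` valid pixels
#' (all three components finite).
#'
#' @param triplets a [stability_triplet()] data.frame.
#' @param landscape a [make_landscape()] result sharing the pixel axis.
#' @param min_pixels minimum valid pixels per unit (default 30).
#' @return Named list of class `spatial_datasets`; one data.frame per
#'   retained unit (rows = pixels, with the triplet columns plus `county_id`
#'   and `grassland_type`), with attribute `n_dropped` giving the number of
#'   discarded units.
#' @export
group_space_for_time <- function(triplets, landscape, min_pixels = 30) {
  if (!nrow(landscape$pixels)) stop("empty landscape", call. = FALSE)
  df <- merge(triplets, landscape$pixels, by = "pixel_id", sort = TRUE)
  if (!nrow(df))
    stop("triplets and landscape share no pixels", call. = FALSE)
  valid <- is.finite(df$invariability_raw) & is.finite(df$resistance_raw) &
    is.finite(df$resilience_raw)
  df <- df[valid, , drop = FALSE]
  sp <- split(df, df$unit_id)
  keep <- vapply(sp, nrow, integer(1)) >= min_pixels
  n_dropped <- sum(!keep)
  if (n_dropped)
    message(n_dropped, " unit(s) dropped below min_pixels = ", min_pixels)
  structure(sp[keep], n_dropped = n_dropped, class = "spatial_datasets")
}

#' Pairwise Pearson correlations among stability components
#'
#' For one spatial dataset, the across-pixel Pearson correlation and
#' two-sided t-test p-value for each pair of the three stability components
#' (invariability-resistance, invariability-resilience,
#' resistance-resilience). Raw component values are used; Pearson correlation
#' is invariant to the linear 0-100 normalization.
#'
#' @param dataset one element of [group_space_for_time()] (a data.frame with
#'   `invariability_raw`, `resistance_raw`, `resilience_raw`), or any
#'   data.frame with those columns and >= 3 rows.
#' @return data.frame with columns `pair`, `r`, `p`; a zero-variance
#'   component yields `NA` for its pairs.
#' @export
pairwise_correlations <- function(dataset) {
  comp <- c("invariability_raw", "resistance_raw", "resilience_raw")
  stopifnot(all(comp %in% names(dataset)))
  if (nrow(dataset) < 3)
    stop("need >= 3 pixels for correlation", call. = FALSE)
  pairs <- list(inv_rst = comp[c(1, 2)], inv_rsl = comp[c(1, 3)],
                rst_rsl = comp[c(2, 3)])
  rows <- lapply(names(pairs), function(nm) {
    x <- dataset[[pairs[[nm]][1]]]
    y <- dataset[[pairs[[nm]][2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(pair = nm, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(pair = nm, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Build the 3x3 stability correlation matrix of a spatial dataset
#'
#' @inheritParams pairwise_correlations
#' @param sig_level if non-`NULL`, correlations with p above this level are
#'   set to 0 before assembling the matrix.
#' @return 3x3 symmetric correlation matrix with unit diagonal, rows/columns
#'   `invariability`, `resistance`, `resilience`.
#' @export
stability_cor_matrix <- function(dataset, sig_level = NULL) {
  pc <- pairwise_correlations(dataset)
  r <- stats::setNames(pc$r, pc$pair)
  if (!is.null(sig_level)) r[!is.na(pc$p) & pc$p > sig_level] <- 0
  if (anyNA(r))
    stop("undefined correlation (zero-variance component)", call. = FALSE)
  m <- diag(3)
  dimnames(m) <- rep(list(c("invariability", "resistance", "resilience")), 2)
  m[1, 2] <- m[2, 1] <- r[["inv_rst"]]
  m[1, 3] <- m[3, 1] <- r[["inv_rsl"]]
  m[2, 3] <- m[3, 2] <- r[["rst_rsl"]]
  m
}

#' Dimensionality of stability from a correlation matrix
#'
#' The three stability components span an ellipsoid whose semi-axes are the
#' square roots of the eigenvalues of their correlation matrix,
#' \eqn{a_i = \lambda_i^{1/2}}. Its volume is
#' \deqn{V = \frac{\pi^{n/2}}{\Gamma(n/2 + 1)} \prod_{i=1}^{n}
#' \lambda_i^{1/2}.}
#' Semi-axes are normalized by the largest so the longest standardized axis
#' is 1, and the normalized volume is divided by the theoretical maximum (the
#' unit-sphere volume), giving the dimensionality
#' \deqn{D = \prod_i (\lambda_i / \lambda_{max})^{1/2} \in [0, 1],}
#' with \eqn{D = 1} when the components are uncorrelated (a perfect sphere;
#' fully independent stability dimensions) and \eqn{D = 0} when they are
#' perfectly coupled (a degenerate, cigar-like ellipsoid).
#'
#' @param matrix a symmetric correlation-type matrix with unit diagonal;
#'   eigenvalues below `-tol` are an error, tiny negatives are clipped to 0.
#' @param tol symmetry/PSD tolerance (default `1e-10`).
#' @return An object of class `stability_ellipsoid`: list with `matrix`,
#'   `eigenvalues` (decreasing), `semi_axes`, `volume`, `dimensionality` and
#'   `n` (matrix dimension).
#' @export
#' @examples
#' ellipsoid_dimensionality(diag(3))$dimensionality          # 1: a sphere
#' m <- matrix(1, 3, 3)
#' ellipsoid_dimensionality(m)$dimensionality                # 0: a cigar
ellipsoid_dimensionality <- function(matrix, tol = 1e-10) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("invalid matrix: must be square", call. = FALSE)
  if (max(abs(matrix - t(matrix))) > tol)
    stop("invalid matrix: not symmetric within tolerance", call. = FALSE)
  if (max(abs(diag(matrix) - 1)) > tol)
    stop("invalid matrix: diagonal must be 1", call. = FALSE)
  n <- nrow(matrix)
  lam <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -tol))
    stop("invalid matrix: not positive semi-definite (eigenvalue ",
         format(min(lam)), ")", call. = FALSE)
  if (any(lam < 0)) {
    message("clipping ", sum(lam < 0), " tiny negative eigenvalue(s) to 0")
    lam[lam < 0] <- 0
  }
  a <- sqrt(lam)
  volume <- pi^(n / 2) / gamma(n / 2 + 1) * prod(a)
  D <- prod(a / a[1])
  structure(list(matrix = matrix, eigenvalues = lam, semi_axes = a,
                 volume = volume, dimensionality = D, n = n),
            class = "stability_ellipsoid")
}

#' @export
print.stability_ellipsoid <- function(x, ...) {
  cat(sprintf("<stability_ellipsoid> n = %d, D = %.4f, V = %.4f\n",
              x$n, x$dimensionality, x$volume))
  cat("eigenvalues:", paste(sprintf("%.4f", x$eigenvalues),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Dimensionality of stability for every spatial dataset
#'
#' @param datasets a [group_space_for_time()] result.
#' @param sig_level passed to [stability_cor_matrix()].
#' @return data.frame with one row per unit: `unit_id`, `county_id`,
#'   `grassland_type`, `n_pixels`, the three pairwise correlations
#'   (`r_inv_rst`, `r_inv_rsl`, `r_rst_rsl`) and their p-values, eigenvalues
#'   `lambda_1..3`, `volume` and `dimensionality`.
#' @export
dimensionality_table <- function(datasets, sig_level = NULL) {
  stopifnot(inherits(datasets, "spatial_datasets"))
  rows <- lapply(names(datasets), function(uid) {
    d <- datasets[[uid]]
    pc <- pairwise_correlations(d)
    ell <- ellipsoid_dimensionality(stability_cor_matrix(d, sig_level))
    data.frame(unit_id = uid, county_id = d$county_id[1],
               grassland_type = d$grassland_type[1], n_pixels = nrow(d),
               r_inv_rst = pc$r[1], p_inv_rst = pc$p[1],
               r_inv_rsl = pc$r[2], p_inv_rsl = pc$p[2],
               r_rst_rsl = pc$r[3], p_rst_rsl = pc$p[3],
               lambda_1 = ell$eigenvalues[1],
               lambda_2 = ell$eigenvalues[2],
               lambda_3 = ell$eigenvalues[3],
               volume = ell$volume,
               dimensionality = ell$dimensionality)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-period change in dimensionality
#'
#' Joins per-unit dimensionalities of two periods, computes
#' \eqn{\Delta D = D_2 - D_1} and summaries: the mean change, the share of
#' units (optionally pixel-weighted) in which dimensionality decreased, and,
#' among those, the share whose relative decrease \eqn{(D_1 - D_2)/D_1}
#' exceeds 20 percent.
#'
#' @param d1,d2 [dimensionality_table()] results for periods 1 and 2 (must
#'   cover the same unit ids).
#' @param weighted weight the unit summaries by pixel count (default `TRUE`).
#' @return List with `per_unit` (data.frame `unit_id`, `d1`, `d2`, `delta`,
#'   `rel_change`, `n_pixels`) and `summary` (named vector: `mean_delta`,
#'   `pct_decreasing`, `pct_decreasing_gt20`).
#' @export
delta_dimensionality <- function(d1, d2, weighted = TRUE) {
  miss1 <- setdiff(d2$unit_id, d1$unit_id)
  miss2 <- setdiff(d1$unit_id, d2$unit_id)
  if (length(miss1) || length(miss2))
    stop("unit mismatch between periods; missing: ",
         paste(unique(c(miss1, miss2)), collapse = ", "), call. = FALSE)
  j <- merge(d1[, c("unit_id", "dimensionality", "n_pixels")],
             d2[, c("unit_id", "dimensionality")],
             by = "unit_id", suffixes = c("_1", "_2"))
  per_unit <- data.frame(unit_id = j$unit_id,
                         d1 = j$dimensionality_1, d2 = j$dimensionality_2,
                         delta = j$dimensionality_2 - j$dimensionality_1,
                         rel_change = (j$dimensionality_2 -
                                         j$dimensionality_1) /
                                      j$dimensionality_1,
                         n_pixels = j$n_pixels)
  w <- if (weighted) per_unit$n_pixels else rep(1, nrow(per_unit))
  dec <- per_unit$delta < 0
  big <- dec & per_unit$rel_change < -0.2
  summary <- c(
    mean_delta = sum(w * per_unit$delta) / sum(w),
    pct_decreasing = 100 * sum(w[dec]) / sum(w),
    pct_decreasing_gt20 = if (any(dec)) 100 * sum(w[big]) / sum(w[dec])
                          else 0)
  list(per_unit = per_unit, summary = summary)
}
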