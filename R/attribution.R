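#' Assemble the attribution table
#'
#' One row per county x grassland-type unit with the between-period changes
#' in climate trends (mean annual temperature, annual precipitation, annual
#' radiation), grazing-intensity trend, and dimensionality. Rows with any
#' missing value are dropped with a warning.
#'
#' @param deltas data.frame with `unit_id` and columns `d_trend_mat`,
#'   `d_trend_ap`, `d_trend_ar`, `d_trend_gi` (period-2 minus period-1 trend
#'   of each driver).
#' @param ddim data.frame with `unit_id` and `delta` (change in
#'   dimensionality), e.g. the `per_unit` element of
#'   [delta_dimensionality()].
#' @return data.frame with `unit_id`, the four predictor columns, and
#'   `d_dimensionality`.
#' @export
assemble_attribution_table <- function(deltas, ddim) {
  pred <- c("d_trend_mat", "d_trend_ap", "d_trend_ar", "d_trend_gi")
  stopifnot(all(c("unit_id", pred) %in% names(deltas)),
            all(c("unit_id", "delta") %in% names(ddim)))
  j <- merge(deltas[, c("unit_id", pred)],
             ddim[, c("unit_id", "delta")], by = "unit_id")
  if (!nrow(j)) stop("empty join: no shared unit ids", call. = FALSE)
  names(j)[names(j) == "delta"] <- "d_dimensionality"
  complete <- stats::complete.cases(j)
  if (any(!complete))
    warning(sum(!complete), " unit(s) dropped for missing values",
            call. = FALSE)
  j[complete, , drop = FALSE]
}

#' Bivariate regressions of dimensionality change on each driver
#'
#' Simple OLS of the change in dimensionality on each predictor separately,
#' returning slope, standard error and two-sided p-value per driver.
#'
#' @param table an [assemble_attribution_table()] result with >= 10 rows.
#' @return data.frame with `predictor`, `slope`, `se`, `p`; a constant
#'   predictor yields `NA` with no error.
#' @export
bivariate_relationships <- function(table) {
  pred <- c("d_trend_mat", "d_trend_ap", "d_trend_ar", "d_trend_gi")
  stopifnot(all(c(pred, "d_dimensionality") %in% names(table)))
  if (nrow(table) < 10)
    stop("need >= 10 rows for bivariate regression", call. = FALSE)
  rows <- lapply(pred, function(v) {
    x <- table[[v]]
    if (stats::sd(x) == 0)
      return(data.frame(predictor = v, slope = NA_real_, se = NA_real_,
                        p = NA_real_))
    fit <- stats::lm(table$d_dimensionality ~ x)
    cf <- summary(fit)$coefficients
    data.frame(predictor = v, slope = cf[2, 1], se = cf[2, 2], p = cf[2, 4])
  })
  do.call(rbind, rows)
}

#' Random-forest attribution of dimensionality change
#'
#' Fits a regression random forest of the change in dimensionality on the
#' four driver-trend changes and reports permutation variable importance
#' (%IncMSE) and the out-of-bag R-squared. Two importance variants are
#' exposed: `"pct_baseline"` (default) expresses the mean out-of-bag MSE
#' increase under per-tree predictor permutation as a percentage of the
#' baseline out-of-bag MSE; `"scaled"` is the conventional
#' mean-increase-divided-by-its-standard-error statistic.
#'
#' @param table an [assemble_attribution_table()] result with >= 20 rows.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; same seed and table give identical importances.
#' @param mtry predictors tried at each split (default one third of 4,
#'   rounded up, i.e. 2).
#' @param variant importance variant, `"pct_baseline"` or `"scaled"`.
#' @return An object of class `attribution_result`: list with `importance`
#'   (named vector, percent for `"pct_baseline"`), `importance_scaled`,
#'   `r_squared` (out-of-bag), `variant`, `n_trees`, `n` and the fitted
#'   `forest`.
#' @export
random_forest_attribution <- function(table, n_trees = 500, seed = 1,
                                      mtry = 2,
                                      variant = c("pct_baseline",
                                                  "scaled")) {
  variant <- match.arg(variant)
  pred <- c("d_trend_mat", "d_trend_ap", "d_trend_ar", "d_trend_gi")
  stopifnot(all(c(pred, "d_dimensionality") %in% names(table)))
  if (nrow(table) < 20)
    stop("insufficient data: need >= 20 rows", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rf <- randomForest::randomForest(
    x = table[, pred], y = table$d_dimensionality,
    ntree = n_trees, mtry = mtry, importance = TRUE, keep.forest = TRUE)
  baseline_mse <- rf$mse[n_trees]
  raw <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  scaled <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  imp <- if (variant == "pct_baseline") 100 * raw / baseline_mse else scaled
  structure(list(importance = imp, importance_scaled = scaled,
                 importance_raw = raw,
                 r_squared = rf$rsq[n_trees], variant = variant,
                 n_trees = n_trees, n = nrow(table), forest = rf),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> n = %d, %d trees, OOB R^2 = %.3f\n",
              x$n, x$n_trees, x$r_squared))
  cat("importance (", x$variant, "):\n", sep = "")
  print(round(x$importance, 2))
  invisible(x)
}
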