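# triplet data.frame with prescribed component values
mk_triplets <- function(inv, rst, rsl, pixel_id = seq_along(inv)) {
  data.frame(pixel_id = pixel_id, invariability_raw = inv,
             resistance_raw = rst, resilience_raw = rsl,
             invariability = NA, resistance = NA, resilience = NA)
}

test_that("space-for-time grouping counts units and enforces the minimum", {
  ls <- make_landscape(3, 2, 10, seed = 1)
  set.seed(2)
  tr <- mk_triplets(rnorm(60), rnorm(60), rnorm(60),
                    pixel_id = ls$pixels$pixel_id)
  g <- group_space_for_time(tr, ls, min_pixels = 5)
  expect_length(g, 6)
  expect_true(all(vapply(g, nrow, integer(1)) == 10))
  # invalidate 6 pixels of one unit: that unit drops below min_pixels = 5
  uid <- ls$pixels$unit_id[1]
  bad <- ls$pixels$pixel_id[ls$pixels$unit_id == uid][1:6]
  tr2 <- tr; tr2$invariability_raw[tr2$pixel_id %in% bad] <- NA
  g2 <- suppressMessages(group_space_for_time(tr2, ls, min_pixels = 5))
  expect_length(g2, 5)
  expect_false(uid %in% names(g2))
  expect_equal(attr(g2, "n_dropped"), 1)
})

test_that("grouping is invariant to pixel order (brute-force group-by oracle)", {
  ls <- make_landscape(2, 3, 8, seed = 3)
  set.seed(4)
  n <- nrow(ls$pixels)
  tr <- mk_triplets(rnorm(n), rnorm(n), rnorm(n),
                    pixel_id = ls$pixels$pixel_id)
  g1 <- group_space_for_time(tr, ls, min_pixels = 2)
  g2 <- group_space_for_time(tr[sample(n), ], ls, min_pixels = 2)
  expect_identical(names(g1), names(g2))
  for (u in names(g1))
    expect_equal(g1[[u]][order(g1[[u]]$pixel_id), ],
                 g2[[u]][order(g2[[u]]$pixel_id), ],
                 ignore_attr = TRUE)
  # oracle: per-unit sizes from a plain table() on the pixel map
  expect_equal(vapply(g1, nrow, integer(1)),
               c(table(ls$pixels$unit_id)), ignore_attr = TRUE)
  expect_error(group_space_for_time(tr, list(pixels = data.frame())),
               "empty landscape")
})

test_that("pairwise Pearson correlations match construction and a brute-force oracle", {
  x <- rnorm(40)
  d <- mk_triplets(2 * x, x, rnorm(40))
  pc <- pairwise_correlations(d)
  expect_equal(pc$r[pc$pair == "inv_rst"], 1, tolerance = 1e-12)
  # independent components at n = 1000 stay near zero
  set.seed(5)
  d0 <- mk_triplets(rnorm(1000), rnorm(1000), rnorm(1000))
  expect_true(all(abs(pairwise_correlations(d0)$r) < 0.1))
  # brute-force covariance/SD oracle on a 10-pixel fixture
  set.seed(6)
  f <- mk_triplets(rnorm(10), rnorm(10), rnorm(10))
  pc10 <- pairwise_correlations(f)
  brute <- function(a, b) mean((a - mean(a)) * (b - mean(b))) /
    (sd(a) * sd(b)) * length(a) / (length(a) - 1)
  expect_equal(pc10$r[1], brute(f$invariability_raw, f$resistance_raw),
               tolerance = 1e-12)
  expect_equal(pc10$r[3], brute(f$resistance_raw, f$resilience_raw),
               tolerance = 1e-12)
  # p-values agree with cor.test
  expect_equal(pc10$p[1], cor.test(f$invariability_raw,
                                   f$resistance_raw)$p.value)
  # zero-variance component flags its pairs
  dz <- mk_triplets(rep(1, 10), rnorm(10), rnorm(10))
  expect_true(all(is.na(pairwise_correlations(dz)$r[c(1, 2)])))
})

test_that("ellipsoid dimensionality hits the analytic endpoints", {
  e1 <- ellipsoid_dimensionality(diag(3))
  expect_identical(e1$dimensionality, 1)
  expect_equal(e1$eigenvalues, rep(1, 3))
  expect_equal(e1$volume, 4 / 3 * pi, tolerance = 1e-12)
  ones <- matrix(1, 3, 3)
  e0 <- suppressMessages(ellipsoid_dimensionality(ones))
  expect_identical(e0$dimensionality, 0)
  expect_equal(e0$eigenvalues[1], 3, tolerance = 1e-12)
  # compound symmetry r = 0.5: eigenvalues 2, 0.5, 0.5 -> D = 0.25
  cs <- diag(3) * 0.5 + 0.5
  ecs <- ellipsoid_dimensionality(cs)
  expect_equal(ecs$eigenvalues, c(2, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(ecs$dimensionality, 0.25, tolerance = 1e-12)
  expect_equal(ecs$semi_axes, sqrt(c(2, 0.5, 0.5)), tolerance = 1e-12)
})

test_that("dimensionality is permutation-invariant and monotone in one correlation", {
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.4; m[1, 3] <- m[3, 1] <- -0.2
  d0 <- ellipsoid_dimensionality(m)$dimensionality
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  for (p in perms)
    expect_equal(ellipsoid_dimensionality(m[p, p])$dimensionality, d0,
                 tolerance = 1e-12)
  # single non-zero r: closed form from eigenvalues (1 + r, 1, 1 - r)
  last <- 1
  for (r in seq(0.1, 0.9, by = 0.1)) {
    mm <- diag(3); mm[1, 2] <- mm[2, 1] <- r
    D <- ellipsoid_dimensionality(mm)$dimensionality
    closed <- sqrt((1 - r) / (1 + r)) * sqrt(1 / (1 + r))
    expect_equal(D, closed, tolerance = 1e-12)
    expect_lt(D, last)
    last <- D
  }
})

test_that("eigenvalues keep unit trace and invalid matrices are rejected", {
  set.seed(7)
  d <- mk_triplets(rnorm(30), rnorm(30), rnorm(30))
  m <- stability_cor_matrix(d)
  e <- ellipsoid_dimensionality(m)
  expect_equal(sum(e$eigenvalues), 3, tolerance = 1e-10)
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(ellipsoid_dimensionality(asym), "not symmetric")
  npsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(ellipsoid_dimensionality(npsd), "positive semi-definite")
  expect_error(ellipsoid_dimensionality(diag(c(1, 2, 1))), "diagonal")
})

test_that("significance filtering can zero weak correlations", {
  set.seed(8)
  d <- mk_triplets(rnorm(12), rnorm(12), rnorm(12))
  m <- stability_cor_matrix(d, sig_level = 1e-6)
  expect_equal(m, diag(3), ignore_attr = TRUE)
})

test_that("delta dimensionality summaries match brute-force enumeration", {
  mk_dim <- function(ids, D, np = 40)
    data.frame(unit_id = ids, dimensionality = D, n_pixels = np)
  ids <- sprintf("u%02d", 1:10)
  # no change anywhere
  eq <- delta_dimensionality(mk_dim(ids, rep(0.5, 10)),
                             mk_dim(ids, rep(0.5, 10)))
  expect_equal(unname(eq$summary["mean_delta"]), 0)
  expect_equal(unname(eq$summary["pct_decreasing"]), 0)
  # uniform decrease of 0.1
  dn <- delta_dimensionality(mk_dim(ids, rep(0.5, 10)),
                             mk_dim(ids, rep(0.4, 10)))
  expect_equal(unname(dn$summary["pct_decreasing"]), 100)
  expect_equal(unname(dn$summary["mean_delta"]), -0.1, tolerance = 1e-12)
  # mixed fixture: 6 decreasing (3 by > 20% relative), 4 increasing
  d1 <- c(0.50, 0.50, 0.50, 0.50, 0.50, 0.50, 0.40, 0.40, 0.40, 0.40)
  d2 <- c(0.45, 0.48, 0.49, 0.30, 0.35, 0.39, 0.45, 0.50, 0.41, 0.60)
  mx <- delta_dimensionality(mk_dim(ids, d1), mk_dim(ids, d2),
                             weighted = FALSE)
  dec <- d2 < d1
  big <- dec & (d1 - d2) / d1 > 0.2
  expect_equal(unname(mx$summary["pct_decreasing"]), 100 * mean(dec))
  expect_equal(unname(mx$summary["pct_decreasing_gt20"]),
               100 * sum(big) / sum(dec))
  # pixel weighting shifts the shares
  w1 <- mk_dim(ids, d1, np = c(rep(10, 5), rep(90, 5)))
  wx <- delta_dimensionality(w1, mk_dim(ids, d2))
  expect_equal(unname(wx$summary["pct_decreasing"]),
               100 * sum(w1$n_pixels[dec]) / sum(w1$n_pixels))
  expect_error(delta_dimensionality(mk_dim(ids, d1),
                                    mk_dim(sprintf("v%02d", 1:10), d2)),
               "unit mismatch")
})

test_that("the coupled preset yields strictly lower dimensionality than the independent one", {
  D <- sapply(c(high = 0, low = 0.8), function(load) {
    cfg <- pipeline_config(n_counties = 2, types_per_county = 2,
                           pixels_per_group = 50, min_pixels = 20,
                           latent_loading = load, seed = 31)
    mean(suppressMessages(
      run_pipeline(cfg))$dimensionality[[1]]$dimensionality)
  })
  expect_lt(D[["low"]], D[["high"]])
})
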