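test_that("landscape has declared group structure and is seed-deterministic", {
  ls <- make_landscape(3, 2, 10, seed = 1)
  expect_equal(nrow(ls$pixels), 60)
  expect_equal(n_groups(ls), 6)
  expect_true(all(table(ls$pixels$unit_id) == 10))
  # every pixel belongs to exactly one county and one type
  expect_false(anyDuplicated(ls$pixels$pixel_id) > 0)
  expect_true(all(ls$counties$area_ha > 0))
  expect_identical(ls, make_landscape(3, 2, 10, seed = 1))
  expect_false(identical(ls$counties$area_ha,
                         make_landscape(3, 2, 10, seed = 2)$counties$area_ha))
})

test_that("degenerate single-pixel landscape is valid", {
  ls <- make_landscape(1, 1, 1, seed = 0)
  expect_equal(nrow(ls$pixels), 1)
  expect_equal(n_groups(ls), 1)
})

test_that("group dropout at county scale keeps every county represented", {
  ls <- make_landscape(122, 3, 5, seed = 7, dropout = 0.44)
  # brute-force enumeration of retained county x type pairs
  brute <- nrow(unique(ls$pixels[, c("county_id", "grassland_type")]))
  expect_equal(n_groups(ls), brute)
  expect_equal(n_groups(ls), 210)   # frozen enumeration at this seed
  expect_setequal(unique(ls$pixels$county_id), 1:122)
})

test_that("landscape rejects non-positive arguments", {
  expect_error(make_landscape(0, 1, 1, seed = 1), "must be >= 1")
  expect_error(make_landscape(1, 4, 1, seed = 1), "cannot exceed")
})

test_that("noise-free climate is exactly periodic and carries exact trends", {
  ls <- make_landscape(1, 1, 3, seed = 1)
  cl <- simulate_climate(ls, 48, noise_sd = 0, trend = 0, seed = 1)
  for (v in cl) expect_equal(v$values[, 1:36], v$values[, 13:48])
  cl2 <- simulate_climate(ls, 120, noise_sd = 0,
                          trend = c(temperature = 0.5, precipitation = 0,
                                    radiation = 0), seed = 1)
  ann <- aggregate_series(cl2$temperature, "annual", "mean")
  sl <- linear_trend(ann$values[1, ], as.numeric(ann$time))$slope
  expect_equal(sl, 0.5, tolerance = 1e-10)
})

test_that("climate is bit-identical under a fixed seed and clipped at 0 mm", {
  ls <- make_landscape(2, 1, 5, seed = 3)
  a <- simulate_climate(ls, 216, noise_sd = 1, seed = 99)
  b <- simulate_climate(ls, 216, noise_sd = 1, seed = 99)
  expect_identical(a, b)
  big <- simulate_climate(ls, 60, noise_sd = c(temperature = 0,
                                               precipitation = 200,
                                               radiation = 0), seed = 1)
  expect_true(all(big$precipitation$values >= 0))
  expect_error(simulate_climate(ls, 12, seed = 1), "at least 24")
})

test_that("null NDVI model emits an identically zero anomaly", {
  ls <- make_landscape(1, 1, 4, seed = 1)
  truth <- make_ground_truth(ls, mean_coef = c(alpha = 0, beta = 0,
                                               gamma = 0, delta = 0),
                             sd_coef = 0, noise_sd = 0, seed = 1)
  cl <- simulate_climate(ls, 36, seed = 1)
  nd <- simulate_ndvi(cl, truth, seed = 1)
  expect_equal(max(abs(nd$anomaly)), 0)
  expect_true(all(nd$values >= 0 & nd$values <= 1))
})

test_that("noiseless anomalies satisfy the recursion and refit exactly", {
  s <- mk_small_study(seed = 5, noise_sd = 0, pixels_per_group = 10,
                      n_months = 60)
  truth0 <- make_ground_truth(s$landscape, sd_coef = 0, noise_sd = 0,
                              seed = 6)
  nd <- simulate_ndvi(s$climate, truth0, seed = 1)
  fit <- fit_on_anomaly_scale(nd, s$climate)
  tr <- truth0$coef
  expect_equal(fit$alpha, tr$alpha, tolerance = 1e-10)
  expect_equal(fit$beta, tr$beta, tolerance = 1e-10)
  expect_equal(fit$gamma, tr$gamma, tolerance = 1e-10)
  expect_equal(fit$delta, tr$delta, tolerance = 1e-10)
  expect_true(all(fit$residual_variance < 1e-20))
})

test_that("noisy coefficients are recovered within 0.05 against an OLS oracle", {
  ls <- make_landscape(2, 2, 10, seed = 2)
  truth <- make_ground_truth(ls, mean_coef = c(alpha = 0.4, beta = 0.3,
                                               gamma = 0.1, delta = 0.3),
                             sd_coef = 0, noise_sd = 0.1, noise_cv = 0,
                             seed = 2)
  cl <- simulate_climate(ls, 216, seed = 2)
  nd <- simulate_ndvi(cl, truth, seed = 2)
  fit <- fit_on_anomaly_scale(nd, cl)
  est <- as.matrix(fit[, c("alpha", "beta", "gamma", "delta")])
  expect_lt(median(abs(est - rep(c(0.4, 0.3, 0.1, 0.3), each = nrow(est)))),
            0.05)
  # independent normal-equations oracle on pixel 1's design matrix
  z <- lapply(cl, function(ts) {
    v <- ts$values[1, ]; (v - mean(v)) / sd(v)
  })
  y <- nd$anomaly[1, ]
  nt <- length(y)
  X <- cbind(z$temperature[2:nt], z$precipitation[2:nt],
             z$radiation[2:nt], y[1:(nt - 1)])
  oracle <- solve(t(X) %*% X, t(X) %*% y[2:nt])
  expect_equal(unname(est[1, ]), as.numeric(oracle), tolerance = 1e-8)
})

test_that("NDVI simulator rejects misaligned axes and nonstationary deltas", {
  s <- mk_small_study(seed = 1, pixels_per_group = 5, n_months = 36)
  bad <- s$climate
  bad$precipitation <- subset_pixels(bad$precipitation, 1:10)
  expect_error(simulate_ndvi(bad, s$truth, seed = 1), "misaligned")
  tr <- s$truth
  tr$coef$delta[1] <- 1.2
  expect_error(simulate_ndvi(s$climate, tr, seed = 1), "nonstationary")
})

test_that("ground truth respects stationarity and latent-factor coupling", {
  ls <- make_landscape(2, 2, 100, seed = 1)
  t0 <- make_ground_truth(ls, latent_loading = 0, seed = 1)
  t8 <- make_ground_truth(ls, latent_loading = 0.8, seed = 1)
  expect_true(all(abs(t0$coef$delta) < 1))
  expect_true(all(t0$coef$noise_sd >= 0))
  # a strong shared factor couples the draws; independence leaves them apart
  expect_gt(abs(cor(t8$coef$alpha, t8$coef$delta)),
            abs(cor(t0$coef$alpha, t0$coef$delta)))
  expect_gt(cor(t8$coef$alpha, t8$coef$beta), 0.4)
})

test_that("livestock counts are constant when trend and noise are zero", {
  ls <- make_landscape(3, 1, 2, seed = 1)
  lv <- simulate_livestock(ls, 2000:2008, trend_per_period = 0,
                           noise_cv = 0, seed = 1)
  expect_true(all(lv[, c("sheep", "goat", "yak", "donkey", "horse")] >= 0))
  for (d in split(lv, lv$county_id))
    for (sp in c("sheep", "goat", "yak", "donkey", "horse"))
      expect_equal(length(unique(d[[sp]])), 1)
})

test_that("emitted livestock reproduce the declared SHU density to rounding", {
  ls <- make_landscape(4, 1, 2, seed = 2)
  lv <- simulate_livestock(ls, 2005, base_shu_density = 0.8,
                           trend_per_period = 0, county_cv = 0.3,
                           noise_cv = 0, seed = 2)
  # recompute GI from emitted heads; rounding each species head count can
  # move SHU by at most 0.5 + 0.5 + 3 * 4 * 0.5 = 7 SHU per county
  gi <- grazing_intensity(to_sheep_units(lv[, 3:7]),
                          ls$counties$area_ha[match(lv$county_id,
                                                    ls$counties$county_id)])
  dens <- to_sheep_units(lv[, 3:7]) / ls$counties$area_ha
  expect_true(all(abs(to_sheep_units(lv[, 3:7]) -
                        gi * ls$counties$area_ha) < 1e-9))
  expect_true(all(abs(dens * ls$counties$area_ha -
                        to_sheep_units(lv[, 3:7])) <= 7))
})

test_that("a declining second-period trend yields per-period GI slopes (~0, <0)", {
  ls <- make_landscape(3, 1, 2, seed = 4)
  lv <- simulate_livestock(ls, 2000:2017, trend_per_period = c(0, -0.03),
                           periods = list(2000:2008, 2009:2017),
                           noise_cv = 0, seed = 4)
  gz <- grazing_trends(lv, ls$counties,
                       periods = list(2000:2008, 2009:2017))
  s1 <- gz$trends$trend_gi[gz$trends$period == 1]
  s2 <- gz$trends$trend_gi[gz$trends$period == 2]
  expect_true(all(abs(s1) < 1e-3))       # flat up to head-count rounding
  expect_true(all(s2 < -0.02))
  # OLS-slope oracle on one county's emitted series
  d <- gz$gi[gz$gi$county_id == 1 & gz$gi$year >= 2009, ]
  x <- d$year - mean(d$year)
  expect_equal(gz$trends$trend_gi[gz$trends$period == 2 &
                                    gz$trends$county_id == 1],
               sum(x * d$gi) / sum(x^2), tolerance = 1e-12)
})

test_that("livestock simulator validates its arguments", {
  ls <- make_landscape(1, 1, 1, seed = 1)
  expect_error(simulate_livestock(ls, integer(0)), "non-empty")
  expect_error(simulate_livestock(ls, c(2001, 2000)), "increasing")
  expect_error(simulate_livestock(ls, 2000, base_shu_density = -1),
               "non-negative")
})

test_that("presets differ only in coupling, not landscape structure", {
  cfg_lo <- pipeline_config(n_counties = 2, types_per_county = 2,
                            pixels_per_group = 10, latent_loading = 0.8,
                            seed = 5)
  cfg_hi <- pipeline_config(n_counties = 2, types_per_county = 2,
                            pixels_per_group = 10, latent_loading = 0,
                            seed = 5)
  a <- simulate_study(cfg_lo); b <- simulate_study(cfg_hi)
  expect_identical(a$landscape, b$landscape)
  expect_identical(a$periods[[1]]$climate, b$periods[[1]]$climate)
  expect_false(identical(a$truth$coef, b$truth$coef))
})
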