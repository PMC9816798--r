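test_that("yield grids stay inside the configured range for every seed", {
  for (seed in 1:8) {
    g <- generate_yield_grid(scene_config(n_rows = 10, n_cols = 12, seed = seed))
    expect_true(all(is.finite(g$values)))
    expect_gte(min(g$values), 1.39)
    expect_lte(max(g$values), 6.75)
  }
})

test_that("yield grids are deterministic and centre-high", {
  cfg <- scene_config(n_rows = 15, n_cols = 15, seed = 11)
  g1 <- generate_yield_grid(cfg)
  g2 <- generate_yield_grid(cfg)
  expect_identical(g1$values, g2$values)
  centre <- g1$values[7:9, 7:9]
  edges <- c(g1$values[1, ], g1$values[15, ], g1$values[, 1], g1$values[, 15])
  expect_gt(mean(centre), mean(edges))
})

test_that("a flat noiseless field degenerates to the range midpoint", {
  g <- generate_yield_grid(scene_config(n_rows = 5, n_cols = 5,
                                        trend_amplitude = 0,
                                        spatial_noise_sd = 0, seed = 1))
  expect_true(all(g$values == (1.39 + 6.75) / 2))
})

test_that("multispectral reflectances are bounded and yield-linked", {
  cfg <- tiny_config(seed = 3)
  s <- simulate_multispectral_series(generate_yield_grid(cfg))
  expect_true(all(s$reflectance >= 0 & s$reflectance <= 1))
  expect_identical(dimnames(s$reflectance)[[2]], multispectral_bands())

  vm <- monthly_composite(s)
  peak <- which.max(apply(vm$values[, "SR", ], 2, mean))
  expect_gt(cor(vm$values[, "SR", peak], s$yield), 0.5)
  expect_gt(cor(vm$values[, "NDWI", peak], s$yield), 0.5)
})

test_that("a noiseless series gives a perfectly monotone SR-yield link", {
  cfg <- scene_config(n_rows = 8, n_cols = 8, noise_sd = 0, seed = 5)
  s <- simulate_multispectral_series(generate_yield_grid(cfg))
  vm <- monthly_composite(s)
  peak <- which.max(apply(vm$values[, "SR", ], 2, mean))
  sr <- vm$values[, "SR", peak]
  expect_equal(cor(sr, s$yield, method = "spearman"), 1)
  expect_gt(cor(sr, s$yield), 0.9)
})

test_that("cloud fractions mix kept and discarded scenes, and a clear sky keeps all", {
  cfg <- scene_config(n_rows = 5, n_cols = 5, scenes_per_month = 4, seed = 2)
  s <- simulate_multispectral_series(generate_yield_grid(cfg))
  expect_true(any(s$scenes$cloud_fraction > 30))
  expect_true(any(s$scenes$cloud_fraction <= 30))

  clear <- simulate_multispectral_series(
    generate_yield_grid(scene_config(n_rows = 5, n_cols = 5,
                                     cloudy_fraction = 0, seed = 2)))
  expect_true(all(clear$scenes$cloud_fraction <= 30))
  # with nothing above the threshold, filtering changes nothing
  expect_equal(monthly_composite(clear, 30)$values,
               monthly_composite(clear, 100)$values)
})

test_that("planted hyperspectral pairs carry the requested correlation sign", {
  wl <- hyperspectral_band_centers()
  swir <- which(wl > 1300)[c(5, 40)]
  cfg_pos <- scene_config(seed = 4, planted_pairs =
                            list(list(i = swir[1], j = swir[2], sign = +1)))
  tb <- simulate_hyperspectral_samples(config = cfg_pos)
  rsi <- compute_pair_index(tb$spectra, swir[1], swir[2], "RSI")
  expect_gt(cor(rsi, tb$yield), 0)

  vis <- c(which.min(abs(wl - 520)), which.min(abs(wl - 780)))
  cfg_neg <- scene_config(seed = 4, planted_pairs =
                            list(list(i = vis[1], j = vis[2], sign = -1)))
  tb2 <- simulate_hyperspectral_samples(config = cfg_neg)
  ndsi <- compute_pair_index(tb2$spectra, vis[1], vis[2], "NDSI")
  expect_lt(cor(ndsi, tb2$yield), 0)
})

test_that("with zero noise the single planted pair is the global |r| extreme", {
  cfg <- single_pair_config(seed = 6, i = 30L, j = 60L, sign = -1,
                            noise_sd = 0)
  tb <- simulate_hyperspectral_samples(config = cfg)
  surf <- pairwise_correlation_surface(tb, "NDSI")
  best <- which(abs(surf$r) == max(abs(surf$r), na.rm = TRUE), arr.ind = TRUE)
  expect_true(any(best[, 1] == 30 & best[, 2] == 60))
})

test_that("hyperspectral generation is reproducible given the seed", {
  cfg <- tiny_config(seed = 9)
  a <- simulate_hyperspectral_samples(config = cfg)
  b <- simulate_hyperspectral_samples(config = cfg)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$yield, b$yield)
})

test_that("management yields peak at 225 kg/ha and rise with irrigation", {
  tb <- generate_management_table(scene_config(seed = 12), n = 400)
  sm <- summarize_management_effects(tb)
  seeding <- sm[sm$factor == "seeding_rate", ]
  seeding <- seeding[order(as.numeric(seeding$level)), ]
  expect_equal(as.numeric(seeding$level[which.max(seeding$mean)]), 225)
  expect_gt(seeding$mean[seeding$level == "225"],
            seeding$mean[which.max(as.numeric(seeding$level))])

  irr <- sm[sm$factor == "irrigation_mm", ]
  irr <- irr[order(as.numeric(irr$level)), ]
  expect_true(all(diff(irr$mean) > 0))
})

test_that("zero effect sizes give identical group means", {
  e <- default_management_effects()
  e$seeding_curvature <- 0; e$irrigation_gain <- 0; e$noise_sd <- 0
  e$tillage[] <- 0; e$fertilizer[] <- 0
  tb <- generate_management_table(scene_config(seed = 13), n = 60, effects = e)
  sm <- summarize_management_effects(tb)
  expect_true(all(abs(sm$mean - sm$mean[1]) < 1e-12))
})
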