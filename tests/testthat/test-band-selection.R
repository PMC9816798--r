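test_that("pair indices satisfy their identities and match the oracle", {
  m <- rbind(c(0.3, 0.1, 0.2), c(0.25, 0.15, 0.4))
  expect_equal(compute_pair_index(m, 1, 1, "SSI"), c(0, 0))
  expect_equal(compute_pair_index(m, 2, 2, "RSI"), c(1, 1))
  expect_equal(compute_pair_index(m, 3, 3, "NDSI"), c(0, 0))

  expect_equal(compute_pair_index(m, 1, 2, "SSI")[1], 0.2)
  expect_equal(compute_pair_index(m, 1, 2, "RSI")[1], 3)
  expect_equal(compute_pair_index(m, 1, 2, "NDSI")[1], 0.5)

  set.seed(7)
  ri <- runif(50, 0.05, 0.9); rj <- runif(50, 0.05, 0.9)
  mm <- cbind(ri, rj)
  expect_equal(compute_pair_index(mm, 1, 2, "SSI"), oracle_ssi(ri, rj),
               ignore_attr = TRUE)
  expect_equal(compute_pair_index(mm, 1, 2, "RSI"), oracle_rsi(ri, rj),
               ignore_attr = TRUE)
  expect_equal(compute_pair_index(mm, 1, 2, "NDSI"), oracle_ndsi(ri, rj),
               ignore_attr = TRUE)

  # band swap: SSI and NDSI negate, RSI reciprocates
  expect_equal(compute_pair_index(mm, 2, 1, "SSI"),
               -compute_pair_index(mm, 1, 2, "SSI"))
  expect_equal(compute_pair_index(mm, 2, 1, "NDSI"),
               -compute_pair_index(mm, 1, 2, "NDSI"))
  expect_equal(compute_pair_index(mm, 2, 1, "RSI"),
               1 / compute_pair_index(mm, 1, 2, "RSI"))

  # guard: non-positive denominators flag the sample, not an error
  bad <- rbind(c(0.2, 0), c(0.3, 0.1))
  expect_true(is.na(compute_pair_index(bad, 1, 2, "RSI")[1]))
})

test_that("correlation surfaces equal brute-force per-pair recomputation", {
  set.seed(21)
  spectra <- matrix(runif(10 * 5, 0.05, 0.8), nrow = 10)
  y <- rnorm(10, 4, 1)
  tb <- list(spectra = spectra, yield = y, band_centers_nm = 1:5)
  for (tp in c("SSI", "RSI", "NDSI")) {
    surf <- pairwise_correlation_surface(tb, tp)
    for (i in 1:5) for (j in 1:5) {
      if (i == j) { expect_true(is.na(surf$r[i, j])); next }
      v <- compute_pair_index(spectra, i, j, tp)
      ct <- suppressWarnings(cor.test(v, y))
      expect_equal(surf$r[i, j], unname(ct$estimate), tolerance = 1e-12)
      expect_equal(surf$p[i, j], ct$p.value, tolerance = 1e-9)
    }
    expect_equal(n_unordered_pairs(surf), 10L)   # 5 * 4 / 2
  }
})

test_that("SSI and NDSI surfaces are antisymmetric in the band pair", {
  tb <- simulate_hyperspectral_samples(config = tiny_config(seed = 31))
  for (tp in c("SSI", "NDSI")) {
    surf <- pairwise_correlation_surface(tb, tp)
    off <- !is.na(surf$r)
    expect_equal(surf$r[off], -t(surf$r)[off], tolerance = 1e-10)
  }
})

test_that("a pair that reproduces yield exactly attains r = 1", {
  set.seed(33)
  spectra <- matrix(runif(12 * 4, 0.1, 0.9), nrow = 12)
  y <- oracle_ndsi(spectra[, 2], spectra[, 4])
  surf <- pairwise_correlation_surface(list(spectra = spectra, yield = y), "NDSI")
  expect_equal(surf$r[2, 4], 1, tolerance = 1e-10)
})

test_that("extreme-pair selection filters by significance and breaks ties", {
  # handmade surface: two identical maxima -> lexicographically smaller wins
  r <- matrix(NA_real_, 4, 4)
  r[1, 3] <- 0.8; r[2, 4] <- 0.8; r[1, 2] <- -0.9; r[3, 4] <- 0.1
  p <- matrix(NA_real_, 4, 4)
  p[!is.na(r)] <- 1e-5
  p[3, 4] <- 0.5
  surf <- structure(list(r = r, p = p, index_type = "NDSI",
                         band_centers_nm = c(400, 500, 600, 700), n = 10),
                    class = "band_pair_surface")
  sel <- select_extreme_pairs(surf, alpha = 0.001)
  expect_equal(c(sel$positive$i, sel$positive$j), c(1, 3))
  expect_equal(c(sel$negative$i, sel$negative$j), c(1, 2))
  expect_equal(sel$positive$wavelength_j_nm, 600)

  # nothing significant -> empty slots with warnings
  p_ns <- p; p_ns[!is.na(p_ns)] <- 0.5
  surf_ns <- surf; surf_ns$p <- p_ns
  expect_warning(expect_warning(
    sel_ns <- select_extreme_pairs(surf_ns, alpha = 0.001),
    "positively"), "negatively")
  expect_null(sel_ns$positive)
  expect_null(sel_ns$negative)

  surf_empty <- surf; surf_empty$r[] <- NA
  expect_error(select_extreme_pairs(surf_empty), "no defined")
})

test_that("a single planted pair is recovered as the selected extreme", {
  cfg <- single_pair_config(seed = 41, i = 100L, j = 150L, sign = +1,
                            noise_sd = 0)
  tb <- simulate_hyperspectral_samples(config = cfg)
  sel <- select_extreme_pairs(pairwise_correlation_surface(tb, "NDSI"))
  expect_equal(c(sel$positive$i, sel$positive$j), c(100, 150))
  expect_gt(sel$positive$r, 0.99)
})

test_that("custom features are pointwise pair indices over dates", {
  cfg <- tiny_config(seed = 51)
  y <- runif(30, 1.39, 6.75)
  tables <- simulate_hyperspectral_dates(y, cfg)
  calib <- simulate_hyperspectral_samples(y, cfg)
  sel <- select_bands(calib)
  feats <- extract_custom_features(tables, sel)
  expect_equal(dim(feats), c(30L, 3L, 4L))
  expect_equal(dimnames(feats)[[2]], c("SSI", "RSI", "NDSI"))

  # matches compute_pair_index applied by hand
  pair <- wheatyield:::dominant_pair(sel$NDSI)
  expect_equal(feats[, "NDSI", 2],
               compute_pair_index(tables[[2]]$spectra, pair$i, pair$j, "NDSI"))

  one <- extract_custom_features(tables[[1]], sel)
  expect_equal(dim(one), c(30L, 3L, 1L))
  expect_equal(ncol(flatten_vi_matrix(feats)), 12L)
})
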