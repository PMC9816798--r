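test_that("index formulas match direct arithmetic on fixed cases", {
  expect_equal(compute_evi(0.05, 0.1, 0.4), 0.75 / 1.625, tolerance = 1e-12)
  expect_equal(round(compute_evi(0.05, 0.1, 0.4), 4), 0.4615)
  expect_equal(compute_evi(0.05, 0.2, 0.2), 0)      # b8 = b4
  expect_equal(compute_evi(0, 0, 0), 0)

  expect_equal(compute_sr(0.1, 0.4), 4)
  expect_equal(compute_sr(0.2, 0.2), 1)
  expect_equal(compute_sr(0.3, 0), 0)

  expect_equal(compute_ndwi(0.4, 0.2), 1 / 3, tolerance = 1e-12)
  expect_equal(compute_ndwi(0.3, 0.3), 0)
  expect_equal(compute_ndwi(0.4, 0), 1)

  expect_equal(compute_rep(0.1, 0.15, 0.25, 0.3), 722.5)
  expect_equal(compute_rep(0.1, 0.2, 0.25, 0.3), 705)  # midpoint hits b5
  b <- 0.2   # b4 = b5 = b7 makes the interpolation numerator vanish
  expect_equal(compute_rep(b, b, 0.4, b), oracle_rep(b, b, 0.4, b))
  expect_equal(compute_rep(b, b, 0.4, b), 705)
})

test_that("index formulas match the oracle on randomized inputs", {
  set.seed(101)
  n <- 1000
  b2 <- runif(n, 0.01, 0.3); b4 <- runif(n, 0.01, 0.4)
  b5 <- runif(n, 0.05, 0.4); b6 <- runif(n, 0.45, 0.6)
  b7 <- runif(n, 0.2, 0.6); b8 <- runif(n, 0.2, 0.8)
  b11 <- runif(n, 0.05, 0.5)
  expect_equal(compute_evi(b2, b4, b8), oracle_evi(b2, b4, b8))
  expect_equal(compute_sr(b4, b8), oracle_sr(b4, b8))
  expect_equal(compute_ndwi(b8, b11), oracle_ndwi(b8, b11))
  expect_equal(compute_rep(b4, b5, b6, b7), oracle_rep(b4, b5, b6, b7))
  # bounds
  expect_true(all(abs(compute_ndwi(b8, b11)) <= 1))
  expect_true(all(compute_sr(b4, b8) >= 0))
})

test_that("denominator guards flag missing instead of erroring", {
  expect_true(is.na(compute_sr(0, 0.4)))
  expect_true(is.na(compute_ndwi(0, 0)))
  expect_true(is.na(compute_rep(0.1, 0.2, 0.2, 0.3)))
  expect_true(is.na(compute_evi(1 / 7.5, 0, 0)))  # denominator exactly zero
})

make_series <- function(cloud, n = 4, seed = 1) {
  # small handmade series: one month per scene grouping given by `month`
  cfg <- scene_config(n_rows = 2, n_cols = 2, scenes_per_month = length(cloud),
                      n_months = 2, seed = seed)
  s <- simulate_multispectral_series(generate_yield_grid(cfg))
  s$scenes$cloud_fraction <- rep(cloud, 2)
  s
}

test_that("compositing averages retained scenes and honours the 30% boundary", {
  s <- make_series(c(0, 10, 31))
  vi <- wheatyield:::scene_vi_values(s)
  vm <- monthly_composite(s, 30)
  month1 <- which(s$scenes$month == 1 & s$scenes$cloud_fraction <= 30)
  manual <- apply(vi[, , month1, drop = FALSE], c(1, 2), mean)
  expect_equal(vm$values[, , 1], manual)

  # a scene at exactly 30.0 is retained; 30 + eps is not
  s2 <- make_series(c(30, 80))
  vm2 <- monthly_composite(s2, 30)
  vi2 <- wheatyield:::scene_vi_values(s2)
  expect_equal(vm2$values[, , 1], vi2[, , 1])

  s3 <- make_series(c(30.0001, 5))
  vm3 <- monthly_composite(s3, 30)
  vi3 <- wheatyield:::scene_vi_values(s3)
  expect_equal(vm3$values[, , 1], vi3[, , 2])
})

test_that("compositing is invariant to scene order", {
  s <- make_series(c(3, 12, 25), seed = 4)
  perm <- c(4, 1, 6, 2, 5, 3)
  s2 <- s
  s2$reflectance <- s$reflectance[, , perm]
  s2$scenes <- s$scenes[perm, ]
  s2$scenes$scene <- seq_len(nrow(s2$scenes))
  expect_equal(monthly_composite(s)$values, monthly_composite(s2)$values)
})

test_that("months with no retained scene are interpolated from neighbours", {
  cfg <- scene_config(n_rows = 2, n_cols = 2, scenes_per_month = 1,
                      n_months = 3, seed = 2)
  s <- simulate_multispectral_series(generate_yield_grid(cfg))
  s$scenes$cloud_fraction <- c(0, 95, 0)   # middle month fully cloudy
  vm <- monthly_composite(s)
  expect_equal(vm$imputed_months, 2L)
  expect_equal(vm$values[, , 2], (vm$values[, , 1] + vm$values[, , 3]) / 2)

  s$scenes$cloud_fraction <- c(95, 95, 95)
  expect_error(monthly_composite(s), "cloud filter")
})

test_that("flattening is index-major, invertible and sized n_vi x n_steps", {
  cfg <- tiny_config(seed = 6)
  vm <- monthly_composite(simulate_multispectral_series(generate_yield_grid(cfg)))
  flat <- flatten_vi_matrix(vm)
  expect_equal(ncol(flat), 36L)
  expect_equal(colnames(flat)[1:9], paste("EVI", vm$months, sep = "_"))
  back <- unflatten_vi_matrix(flat, 4, 9, vi = vi_names(), steps = vm$months)
  expect_equal(back, vm$values, ignore_attr = FALSE)

  a <- array(rnorm(2 * 3 * 4), c(2, 3, 4),
             dimnames = list(NULL, c("SSI", "RSI", "NDSI"), paste0("d", 1:4)))
  expect_equal(ncol(flatten_vi_matrix(a)), 12L)
  # explicit order check on a hand-built array
  expect_equal(unname(flatten_vi_matrix(a)[1, ]), as.vector(t(a[1, , ])))

  a[1, 1, 1] <- NA
  expect_error(flatten_vi_matrix(a), "missing")
})
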