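#' Band names of the simulated multispectral sensor
#'
#' The eight bands used throughout: blue (B2), green (B3), red (B4), three
#' red-edge bands (B5-B7), wide near-infrared (B8) and shortwave infrared
#' (B11).
#' @return Character vector of length 8.
#' @export
multispectral_bands <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B11")
}

#' Month labels of the winter wheat season
#' @param n_months Number of monthly steps (default 9, October to June).
#' @return Character vector of month abbreviations starting in October.
#' @export
season_months <- function(n_months = 9) {
  rep(c("Oct", "Nov", "Dec", "Jan", "Feb", "Mar", "Apr", "May", "Jun"),
      length.out = n_months)
}

# canopy phenology shapes over the season (sowing -> overwinter -> green-up
# -> heading -> senescence), interpolated to n_months steps
phenology_shape <- function(n_months, what = c("green", "water")) {
  what <- match.arg(what)
  anchor <- switch(what,
    green = c(0.15, 0.22, 0.20, 0.18, 0.25, 0.55, 0.90, 1.00, 0.55),
    water = c(0.20, 0.28, 0.25, 0.22, 0.30, 0.60, 0.95, 1.00, 0.70))
  stats::approx(seq(0, 1, length.out = 9), anchor,
                xout = seq(0, 1, length.out = n_months))$y
}

#' Simulate a multispectral reflectance time series for every grid cell
#'
#' Each valid grid cell becomes one sample. Two latent canopy trajectories
#' (greenness and water status) follow the seasonal phenology shape scaled
#' by a monotone (affine) function of the cell's yield; the eight band
#' reflectances are affine maps of the latents chosen so that downstream
#' greenness indices (SR, EVI) and the water index (NDWI) correlate
#' positively with yield. Gaussian reflectance noise is added per scene and
#' values are clamped to `[0, 1]`. Each month carries
#' `config$scenes_per_month` acquisitions, and every scene draws a cloud
#' cover fraction from a two-component mixture (mostly-clear vs cloudy) so
#' that cloud filtering has work to do.
#'
#' @param grid A [generate_yield_grid()] result.
#' @param config A [scene_config()]; defaults to the grid's own config.
#' @return An object of class `ms_series`: list with `reflectance` (array
#'   `samples x 8 bands x scenes`, in `[0, 1]`), `scenes` (data.frame with
#'   `scene`, `month` (1-based step), `cloud_fraction` in percent), `yield`
#'   (t/ha per sample) and `months` (labels).
#' @examples
#' cfg <- scene_config(n_rows = 6, n_cols = 6, seed = 2)
#' s <- simulate_multispectral_series(generate_yield_grid(cfg))
#' dim(s$reflectance)
#' @export
simulate_multispectral_series <- function(grid, config = grid$config) {
  stopifnot(inherits(grid, "yield_grid"))
  config <- validate_scene_config(config)
  set.seed(config$seed + 1L)

  y <- grid_yields(grid)
  n <- length(y)
  yn <- (y - config$yield_min) / (config$yield_max - config$yield_min)
  yn <- pmin(pmax(yn, 0), 1)

  n_scenes <- config$n_months * config$scenes_per_month
  month_of <- rep(seq_len(config$n_months), each = config$scenes_per_month)
  g_shape <- phenology_shape(config$n_months, "green")
  w_shape <- phenology_shape(config$n_months, "water")

  bands <- multispectral_bands()
  refl <- array(NA_real_, dim = c(n, length(bands), n_scenes),
                dimnames = list(NULL, bands, NULL))

  for (s in seq_len(n_scenes)) {
    m <- month_of[s]
    g <- g_shape[m] * (0.25 + 0.75 * yn)   # greenness latent, in (0, 1)
    w <- w_shape[m] * (0.25 + 0.75 * yn)   # water latent
    b4 <- 0.30 - 0.22 * g
    b8 <- 0.15 + 0.45 * g
    d <- b8 - b4
    x <- cbind(
      B2 = 0.22 - 0.14 * g,
      B3 = 0.26 - 0.14 * g,
      B4 = b4,
      # red-edge bands sit between red and NIR; the B5 fraction shifts with
      # greenness so the red-edge position moves with canopy chlorophyll
      B5 = b4 + (0.28 - 0.06 * g) * d,
      B6 = b4 + 0.55 * d,
      B7 = b4 + 0.85 * d,
      B8 = b8,
      B11 = 0.35 - 0.25 * w
    )
    if (config$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd), nrow = n)
    }
    refl[, , s] <- pmin(pmax(x, 0), 1)
  }

  cloudy <- stats::runif(n_scenes) < config$cloudy_fraction
  cloud <- ifelse(cloudy, stats::runif(n_scenes, 35, 90),
                  stats::runif(n_scenes, 0, 25))

  structure(
    list(reflectance = refl,
         scenes = data.frame(scene = seq_len(n_scenes), month = month_of,
                             cloud_fraction = cloud),
         yield = y,
         months = season_months(config$n_months),
         config = config),
    class = "ms_series"
  )
}

#' @export
print.ms_series <- function(x, ...) {
  cat(sprintf("<ms_series> %d samples x %d bands x %d scenes (%d months)\n",
              dim(x$reflectance)[1], dim(x$reflectance)[2],
              dim(x$reflectance)[3], length(x$months)))
  cat(sprintf("  cloud cover: %.0f%% of scenes above 30%%\n",
              100 * mean(x$scenes$cloud_fraction > 30)))
  invisible(x)
}

#' Simulate vegetation-index trajectories with one dominant index
#'
#' Builds ready-made model inputs (`samples x months x indices`) in which a
#' single designated index carries the yield signal through the *shape* of
#' its temporal trajectory, while the remaining indices are uninformative
#' smooth noise. Yield depends nonlinearly on the dominant trajectory (its
#' seasonal peak and the timing-weighted accumulation), which a sequence
#' model can exploit but a flattened linear view cannot recover trivially.
#' Used to probe permutation feature importance and model comparisons under
#' a known ground truth.
#'
#' @param n Number of samples.
#' @param n_months Time steps (default 9).
#' @param n_vi Number of index features (default 4).
#' @param dominant Index (1-based) of the informative feature.
#' @param noise_sd Standard deviation of additive trajectory noise.
#' @param yield_range Length-2 yield range (t/ha).
#' @param seed RNG seed.
#' @return List with `x` (array `n x n_months x n_vi`), `y` (yields, t/ha),
#'   `dominant`, and `vi_names`.
#' @export
simulate_vi_sequences <- function(n, n_months = 9, n_vi = 4, dominant = 1,
                                  noise_sd = 0.05,
                                  yield_range = c(1.39, 6.75), seed = 1L) {
  stopifnot(n >= 4, n_vi >= 1, dominant >= 1, dominant <= n_vi)
  set.seed(as.integer(seed))
  tt <- seq(0, 1, length.out = n_months)
  vi_names <- paste0("VI", seq_len(n_vi))

  x <- array(NA_real_, c(n, n_months, n_vi),
             dimnames = list(NULL, season_months(n_months), vi_names))
  amp <- stats::runif(n, 0.3, 1)           # per-sample seasonal amplitude
  peak <- stats::runif(n, 0.55, 0.9)       # per-sample timing of the peak
  for (k in seq_len(n_vi)) {
    if (k == dominant) {
      traj <- outer(seq_len(n), tt, function(i, t) {
        amp[i] * exp(-((t - peak[i]) / 0.22)^2)
      })
    } else {
      a <- stats::runif(n, 0.3, 1)
      p <- stats::runif(n, 0.3, 0.9)
      traj <- outer(seq_len(n), tt, function(i, t) {
        a[i] * exp(-((t - p[i]) / 0.25)^2)
      })
      traj <- traj[sample.int(n), , drop = FALSE]  # decouple from yield
    }
    x[, , k] <- traj + matrix(stats::rnorm(n * n_months, sd = noise_sd), n)
  }

  # yield: nonlinear in the dominant trajectory's amplitude and timing
  signal <- amp^1.5 * (0.6 + 0.4 * sin(3 * peak))
  sig <- (signal - min(signal)) / (max(signal) - min(signal) + 1e-12)
  y <- yield_range[1] + sig * diff(yield_range)

  list(x = x, y = y, dominant = dominant, vi_names = vi_names)
}
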