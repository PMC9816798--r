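#' Band centres of the simulated hyperspectral sensor
#'
#' 76 VNIR bands spanning 396-1040 nm (~8.6 nm spacing) and 90 SWIR bands
#' spanning 1006-2501 nm (~16.8 nm spacing); the three SWIR bands that fall
#' inside the VNIR range are dropped as spectral overlaps, leaving 163
#' effective bands — the band grid of a spaceborne VNIR/SWIR imaging
#' spectrometer after splicing.
#'
#' @return Strictly increasing numeric vector of 163 wavelengths (nm).
#' @examples
#' length(hyperspectral_band_centers())
#' @export
hyperspectral_band_centers <- function() {
  vnir <- seq(396, 1040, length.out = 76)
  swir <- seq(1006, 2501, length.out = 90)
  swir <- swir[swir > max(vnir)]   # drop the 3 overlapping SWIR bands
  wl <- c(vnir, swir)
  stopifnot(length(wl) == 163L, !is.unsorted(wl, strictly = TRUE))
  wl
}

# smooth vegetation-like baseline reflectance at the given wavelengths:
# low visible with a green bump, red-edge rise, NIR plateau, SWIR decline
# with the 1450/1940 nm water absorption dips
baseline_spectrum <- function(wl) {
  anchors_nm <- c(396, 450, 520, 560, 650, 680, 720, 760, 900, 1040,
                  1200, 1450, 1660, 1940, 2200, 2501)
  anchors_r <- c(0.04, 0.05, 0.09, 0.11, 0.06, 0.05, 0.25, 0.42, 0.45, 0.44,
                 0.42, 0.16, 0.30, 0.10, 0.22, 0.12)
  stats::spline(anchors_nm, anchors_r, xout = wl, method = "natural")$y
}

#' Simulate single-date hyperspectral spectra with planted yield signals
#'
#' Each sample receives a smooth vegetation baseline spectrum plus Gaussian
#' band noise. For every planted pair `(i, j, sign)` in the config, a
#' yield-linked perturbation of amplitude `planted_amplitude` is added to
#' band `i` and subtracted from band `j` (or vice versa for `sign = -1`), so
#' the two-band difference, ratio and normalized-difference indices of that
#' pair all correlate with yield with the requested sign. All other bands
#' carry baseline plus noise only.
#'
#' @param yields Numeric vector of sample yields (t/ha). If omitted, yields
#'   are drawn uniformly over the config's range for
#'   `config$n_hyper_samples` samples.
#' @param config A [scene_config()].
#' @param date_strength Multiplier on the planted amplitude, used to modulate
#'   the signal across acquisition dates.
#' @param seed_offset Integer added to the config seed, so different
#'   acquisition dates yield different noise realizations.
#' @return An object of class `hs_table`: list with `spectra` (matrix
#'   `samples x 163`), `band_centers_nm`, and `yield`.
#' @examples
#' tb <- simulate_hyperspectral_samples(config = scene_config(seed = 3))
#' dim(tb$spectra)
#' @export
simulate_hyperspectral_samples <- function(yields = NULL, config,
                                           date_strength = 1,
                                           seed_offset = 0L) {
  config <- validate_scene_config(config)
  set.seed(config$seed + 2L + as.integer(seed_offset))
  if (is.null(yields)) {
    yields <- stats::runif(config$n_hyper_samples,
                           config$yield_min, config$yield_max)
  }
  n <- length(yields)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  yn <- (yields - config$yield_min) / (config$yield_max - config$yield_min)
  yn <- pmin(pmax(yn, 0), 1)

  wl <- hyperspectral_band_centers()
  base <- baseline_spectrum(wl)
  spectra <- matrix(rep(base, each = n), nrow = n,
                    dimnames = list(NULL, sprintf("nm_%.6f", wl)))
  if (config$noise_sd > 0) {
    spectra <- spectra +
      matrix(stats::rnorm(length(spectra), sd = config$noise_sd), nrow = n)
  }
  amp <- config$planted_amplitude * date_strength
  for (p in config$planted_pairs) {
    delta <- p$sign * amp * (yn - 0.5)
    spectra[, p$i] <- spectra[, p$i] + delta
    spectra[, p$j] <- spectra[, p$j] - delta
  }
  spectra <- pmin(pmax(spectra, 1e-3), 1)   # keep strictly positive for RSI

  structure(
    list(spectra = spectra, band_centers_nm = wl, yield = as.numeric(yields)),
    class = "hs_table"
  )
}

#' @export
print.hs_table <- function(x, ...) {
  cat(sprintf("<hs_table> %d samples x %d bands (%.0f-%.0f nm)\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$band_centers_nm), max(x$band_centers_nm)))
  invisible(x)
}

#' Simulate a multi-date hyperspectral acquisition series
#'
#' Generates one [simulate_hyperspectral_samples()] table per acquisition
#' date for a common set of samples. The planted-signal strength follows a
#' mild phenological ramp across dates so that later (closer to heading)
#' acquisitions are slightly more informative.
#'
#' @param yields Yields (t/ha), shared across dates.
#' @param config A [scene_config()].
#' @param dates Character vector of date labels (default the four spring
#'   acquisition dates of the field campaign).
#' @return Named list of `hs_table` objects, one per date.
#' @export
simulate_hyperspectral_dates <- function(yields, config,
                                         dates = c("2021-03-24", "2021-03-30",
                                                   "2021-04-28", "2021-05-01")) {
  strengths <- seq(0.8, 1.1, length.out = length(dates))
  out <- lapply(seq_along(dates), function(k) {
    simulate_hyperspectral_samples(yields, config,
                                   date_strength = strengths[k],
                                   seed_offset = 10L * k)
  })
  names(out) <- dates
  out
}
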