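#' Scene configuration for the synthetic study area
#'
#' Bundles every knob of the synthetic data generators: grid geometry, the
#' monthly acquisition calendar, the hyperspectral sampling design, the yield
#' range observed in the field campaign and the reflectance noise model.
#' Downstream generators ([generate_yield_grid()],
#' [simulate_multispectral_series()], [simulate_hyperspectral_samples()],
#' [generate_management_table()]) take a `scene_config` and are fully
#' deterministic given its `seed`.
#'
#' @param n_rows,n_cols Grid dimensions (cells). Defaults give a small grid
#'   suitable for tests; the full-campaign scale (~15,700 cells at 5 m) is
#'   reached with e.g. `n_rows = 125, n_cols = 126`.
#' @param cell_size_m Cell edge length in metres.
#' @param origin Numeric length-2, map coordinates (x, y) of the upper-left
#'   corner of the grid.
#' @param n_months Number of monthly time steps in the growing season,
#'   October through June by default (9 steps).
#' @param scenes_per_month Satellite acquisitions simulated per month; more
#'   than one is needed to exercise cloud filtering and compositing.
#' @param n_hyper_samples Number of ground sample points carrying a
#'   hyperspectral spectrum (the field campaign used 39).
#' @param yield_min,yield_max Yield range in t/ha; the field campaign
#'   observed 1.39 to 6.75 t/ha.
#' @param trend_amplitude Relative strength of the centre-high/edge-low
#'   spatial yield trend in `[0, 1]`. `0` gives a flat field.
#' @param spatial_noise_sd Standard deviation of the spatially correlated
#'   yield noise, on the latent (pre-rescaling) scale.
#' @param noise_sd Standard deviation of additive Gaussian reflectance noise
#'   (reflectance units, so 0.01 is a 1% reflectance perturbation).
#' @param cloudy_fraction Probability that a simulated scene is drawn from
#'   the cloudy component of the cloud-cover mixture (cover > 30%).
#' @param planted_pairs List of informative hyperspectral band pairs, each a
#'   list or vector with elements `i`, `j` (1-based band indices into the
#'   163-band grid) and `sign` (+1 or -1), giving the sign of the correlation
#'   between the pair's two-band indices and yield. The default plants one
#'   visible/NIR pair with a negative association and one SWIR pair with a
#'   positive association, matching the spectral structure reported for
#'   winter wheat.
#' @param planted_amplitude Reflectance amplitude of the planted yield signal.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `scene_config` (a validated list).
#' @examples
#' cfg <- scene_config(n_rows = 10, n_cols = 10, seed = 1)
#' cfg$yield_max
#' @export
scene_config <- function(n_rows = 25,
                         n_cols = 40,
                         cell_size_m = 5,
                         origin = c(0, 0),
                         n_months = 9,
                         scenes_per_month = 3,
                         n_hyper_samples = 39,
                         yield_min = 1.39,
                         yield_max = 6.75,
                         trend_amplitude = 1,
                         spatial_noise_sd = 0.15,
                         noise_sd = 0.01,
                         cloudy_fraction = 0.3,
                         planted_pairs = default_planted_pairs(),
                         planted_amplitude = 0.08,
                         seed = 1L) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    cell_size_m = cell_size_m, origin = as.numeric(origin),
    n_months = as.integer(n_months),
    scenes_per_month = as.integer(scenes_per_month),
    n_hyper_samples = as.integer(n_hyper_samples),
    yield_min = yield_min, yield_max = yield_max,
    trend_amplitude = trend_amplitude,
    spatial_noise_sd = spatial_noise_sd,
    noise_sd = noise_sd,
    cloudy_fraction = cloudy_fraction,
    planted_pairs = normalize_planted_pairs(planted_pairs),
    planted_amplitude = planted_amplitude,
    seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  grid: %d x %d cells @ %g m\n", x$n_rows, x$n_cols, x$cell_size_m))
  cat(sprintf("  season: %d monthly steps, %d scene(s)/month\n",
              x$n_months, x$scenes_per_month))
  cat(sprintf("  yield range: [%g, %g] t/ha\n", x$yield_min, x$yield_max))
  cat(sprintf("  hyperspectral: %d samples, %d planted pair(s)\n",
              x$n_hyper_samples, length(x$planted_pairs)))
  cat(sprintf("  noise_sd: %g, seed: %d\n", x$noise_sd, x$seed))
  invisible(x)
}

validate_scene_config <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (cfg$n_rows < 1L || cfg$n_cols < 1L) {
    stop("grid dimensions must be positive (got ", cfg$n_rows, " x ",
         cfg$n_cols, ")", call. = FALSE)
  }
  if (cfg$n_months < 2L) {
    stop("n_months must be at least 2", call. = FALSE)
  }
  if (cfg$scenes_per_month < 1L) stop("scenes_per_month must be >= 1", call. = FALSE)
  if (cfg$n_hyper_samples < 3L) stop("n_hyper_samples must be >= 3", call. = FALSE)
  if (!(cfg$yield_min < cfg$yield_max)) {
    stop("yield_min must be strictly less than yield_max", call. = FALSE)
  }
  for (nm in c("spatial_noise_sd", "noise_sd", "planted_amplitude")) {
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (cfg$trend_amplitude < 0 || cfg$trend_amplitude > 1) {
    stop("trend_amplitude must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$cloudy_fraction < 0 || cfg$cloudy_fraction > 1) {
    stop("cloudy_fraction must lie in [0, 1]", call. = FALSE)
  }
  n_bands <- length(hyperspectral_band_centers())
  for (p in cfg$planted_pairs) {
    if (p$i == p$j) stop("planted pair with i == j is not informative", call. = FALSE)
    if (p$i < 1 || p$j < 1 || p$i > n_bands || p$j > n_bands) {
      stop("planted pair indices must reference the ", n_bands,
           "-band grid", call. = FALSE)
    }
    if (!p$sign %in% c(-1, 1)) stop("planted pair sign must be +1 or -1", call. = FALSE)
  }
  cfg
}

normalize_planted_pairs <- function(pairs) {
  lapply(pairs, function(p) {
    p <- as.list(p)
    if (is.null(names(p)) || !all(c("i", "j", "sign") %in% names(p))) {
      names(p) <- c("i", "j", "sign")
    }
    list(i = as.integer(p$i), j = as.integer(p$j), sign = as.numeric(p$sign))
  })
}

#' Default informative band pairs for the hyperspectral generator
#'
#' One visible/NIR pair (bands nearest 516 and 765 nm) planted with a
#' negative yield association, and one SWIR pair (nearest 1375 and 1896 nm)
#' with a positive association. These mirror the sign structure found in
#' winter wheat canopies: chlorophyll-driven visible/NIR combinations
#' anti-correlate with yield while narrow SWIR combinations correlate
#' positively.
#'
#' @return A list of pairs, each `list(i, j, sign)` with 1-based indices into
#'   [hyperspectral_band_centers()].
#' @export
default_planted_pairs <- function() {
  wl <- hyperspectral_band_centers()
  near <- function(nm) which.min(abs(wl - nm))
  list(
    list(i = near(516), j = near(765), sign = -1),
    list(i = near(1375), j = near(1896), sign = +1)
  )
}
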