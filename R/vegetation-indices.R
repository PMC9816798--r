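#' Vegetation indices from multispectral reflectance
#'
#' The four indices used as model features, each from named sensor bands
#' (see [multispectral_bands()]):
#'
#' * `compute_evi()` — enhanced vegetation index (Huete's three-band form),
#'   `2.5 * (B8 - B4) / (B8 + 6*B4 - 7.5*B2 + 1)`; a greenness index robust
#'   to soil background and residual aerosol via the blue band.
#' * `compute_sr()` — simple ratio `B8 / B4`, the classic NIR/red greenness
#'   ratio closely tied to leaf area.
#' * `compute_ndwi()` — normalized difference water index
#'   `(B8 - B11) / (B8 + B11)`, tracking canopy water content via the SWIR
#'   band; bounded in `[-1, 1]`.
#' * `compute_rep()` — red-edge position by linear interpolation between the
#'   red-edge bands, `705 + 35 * (0.5*(B4 + B7) - B5) / (B6 - B5)`,
#'   in nanometres; shifts with chlorophyll content.
#'
#' All functions are vectorized and guard their denominators: an undefined
#' value (|denominator| below `eps`, or a negative `b4` for SR) is returned
#' as `NA` rather than raising an error, so missing scenes flow through the
#' compositing stage.
#'
#' @param b2,b4,b5,b6,b7,b8,b11 Reflectances in `[0, 1]` for the blue, red,
#'   red-edge 1-3, NIR and SWIR bands.
#' @param eps Denominator guard threshold.
#' @return Numeric vector; `NA` where the index is undefined.
#' @examples
#' compute_evi(0.05, 0.1, 0.4)
#' compute_sr(0.1, 0.4)
#' compute_ndwi(0.4, 0.2)
#' compute_rep(0.1, 0.15, 0.25, 0.3)
#' @name vegetation_indices
NULL

#' @rdname vegetation_indices
#' @export
compute_evi <- function(b2, b4, b8, eps = 1e-9) {
  den <- b8 + 6 * b4 - 7.5 * b2 + 1
  out <- 2.5 * (b8 - b4) / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' @rdname vegetation_indices
#' @export
compute_sr <- function(b4, b8, eps = 1e-9) {
  out <- b8 / b4
  out[b4 < eps] <- NA_real_
  out
}

#' @rdname vegetation_indices
#' @export
compute_ndwi <- function(b8, b11, eps = 1e-9) {
  den <- b8 + b11
  out <- (b8 - b11) / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' @rdname vegetation_indices
#' @export
compute_rep <- function(b4, b5, b6, b7, eps = 1e-9) {
  den <- b6 - b5
  out <- 705 + 35 * (0.5 * (b4 + b7) - b5) / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' Names of the composited vegetation indices
#' @return `c("EVI", "SR", "NDWI", "REP")`.
#' @export
vi_names <- function() c("EVI", "SR", "NDWI", "REP")

# per-scene VI values for one ms_series: array samples x vi x scenes
scene_vi_values <- function(series) {
  r <- series$reflectance
  n <- dim(r)[1]; n_scenes <- dim(r)[3]
  out <- array(NA_real_, c(n, 4L, n_scenes),
               dimnames = list(NULL, vi_names(), NULL))
  for (s in seq_len(n_scenes)) {
    x <- matrix(r[, , s], nrow = n, dimnames = list(NULL, dimnames(r)[[2]]))
    out[, "EVI", s] <- compute_evi(x[, "B2"], x[, "B4"], x[, "B8"])
    out[, "SR", s] <- compute_sr(x[, "B4"], x[, "B8"])
    out[, "NDWI", s] <- compute_ndwi(x[, "B8"], x[, "B11"])
    out[, "REP", s] <- compute_rep(x[, "B4"], x[, "B5"], x[, "B6"], x[, "B7"])
  }
  out
}
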