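#' Generate a gridded winter wheat yield surface
#'
#' Produces a smooth spatial yield field with the centre-high/edge-low
#' pattern typical of managed experimental plots (edge effects from tracks,
#' trees and turning machinery), plus spatially correlated noise, rescaled
#' exactly into `[yield_min, yield_max]`.
#'
#' The field is built as `trend_amplitude * dome + noise`, where `dome` is a
#' radially decreasing quadratic of the scaled distance from the grid centre
#' and `noise` is white Gaussian noise smoothed with a separable 5-cell
#' moving-average kernel (giving short-range spatial correlation). The latent
#' field is then linearly mapped onto the configured yield range; a
#' degenerate latent field (zero trend and zero noise) maps to the midpoint
#' of the range.
#'
#' @param config A [scene_config()].
#' @return An object of class `yield_grid`: list with `values` (an
#'   `n_rows x n_cols` matrix, t/ha), `mask` (logical matrix, `TRUE` =
#'   valid cell), `origin`, `cell_size_m`, and the generating `config`.
#' @examples
#' g <- generate_yield_grid(scene_config(n_rows = 12, n_cols = 12, seed = 7))
#' range(g$values)
#' @export
generate_yield_grid <- function(config) {
  config <- validate_scene_config(config)
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols

  rr <- if (nr > 1) (seq_len(nr) - (nr + 1) / 2) / ((nr - 1) / 2) else 0
  cc <- if (nc > 1) (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2) else 0
  d2 <- outer(rr^2, cc^2, `+`)          # squared scaled radius, 0 centre
  dome <- 1 - d2 / max(d2, 1e-12)

  noise <- matrix(stats::rnorm(nr * nc, sd = config$spatial_noise_sd), nr, nc)
  if (config$spatial_noise_sd > 0 && min(nr, nc) >= 5) {
    noise <- smooth_matrix(noise, half_width = 2L)
  }

  latent <- config$trend_amplitude * dome + noise
  span <- max(latent) - min(latent)
  if (span < 1e-12) {
    values <- matrix((config$yield_min + config$yield_max) / 2, nr, nc)
  } else {
    values <- config$yield_min +
      (latent - min(latent)) / span * (config$yield_max - config$yield_min)
  }

  structure(
    list(values = values,
         mask = matrix(TRUE, nr, nc),
         origin = config$origin,
         cell_size_m = config$cell_size_m,
         config = config),
    class = "yield_grid"
  )
}

# separable moving-average smoother; window truncated at the grid edge
smooth_matrix <- function(m, half_width = 2L) {
  smooth_1d <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(t) {
      mean(v[max(1L, t - half_width):min(n, t + half_width)])
    }, numeric(1))
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(t(m), 2, smooth_1d))
}

#' @export
print.yield_grid <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<yield_grid> %d x %d cells @ %g m, %d valid\n",
              nrow(x$values), ncol(x$values), x$cell_size_m, sum(x$mask)))
  cat(sprintf("  yield: %.2f-%.2f t/ha (mean %.2f)\n",
              min(v), max(v), mean(v)))
  invisible(x)
}

#' Extract the per-cell yields of the valid cells
#'
#' @param grid A [generate_yield_grid()] result.
#' @return Numeric vector of yields (t/ha), column-major over valid cells.
#' @export
grid_yields <- function(grid) {
  stopifnot(inherits(grid, "yield_grid"))
  as.numeric(grid$values[grid$mask])
}
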