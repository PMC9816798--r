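#' Write a gridded yield map as a georeferenced TIFF
#'
#' Writes per-cell values as a 32-bit float single-band TIFF together with
#' an ESRI world file (`.tfw`) carrying the affine georeference and a JSON
#' sidecar (`.json`) recording the value scaling, the nodata encoding, the
#' cell size and the origin. Values are affinely packed into `[0.1, 1]`
#' inside the TIFF (the float TIFF writer's value domain); masked cells are
#' stored as the declared nodata value `0`. [read_yield_map()] reverses the
#' packing exactly up to float32 precision.
#'
#' @param grid A [generate_yield_grid()] `yield_grid` supplying geometry and
#'   mask.
#' @param values Optional matrix or vector of values to write (e.g. model
#'   predictions); defaults to the grid's own yields. A vector must match
#'   the number of valid cells and is placed into the mask in column-major
#'   order.
#' @param path Output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_yield_map <- function(grid, values = NULL, path) {
  stopifnot(inherits(grid, "yield_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (is.null(values)) values <- grid$values
  if (is.null(dim(values))) {
    if (length(values) != sum(grid$mask)) {
      stop("prediction length ", length(values), " does not match the ",
           sum(grid$mask), " valid cells", call. = FALSE)
    }
    m <- matrix(NA_real_, nr, nc)
    m[grid$mask] <- values
    values <- m
  }
  if (!all(dim(values) == c(nr, nc))) {
    stop("value matrix shape does not match the grid", call. = FALSE)
  }
  v <- values[grid$mask]
  lo <- min(v); hi <- max(v)
  span <- if (hi - lo < 1e-12) 1 else hi - lo
  packed <- matrix(0, nr, nc)                     # nodata = 0
  packed[grid$mask] <- pmin(pmax(0.1 + 0.9 * (values[grid$mask] - lo) / span,
                                 0), 1)

  tiff::writeTIFF(packed, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  # world file: cell size, rotation terms, centre of the upper-left cell
  tfw <- c(grid$cell_size_m, 0, 0, -grid$cell_size_m,
           grid$origin[1] + grid$cell_size_m / 2,
           grid$origin[2] - grid$cell_size_m / 2)
  writeLines(format(tfw, scientific = FALSE), sub("\\.tiff?$", ".tfw", path))
  jsonlite::write_json(
    list(value_min = lo, value_span = span, nodata = 0,
         cell_size_m = grid$cell_size_m, origin = grid$origin,
         n_rows = nr, n_cols = nc, units = "t/ha"),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a yield map written by [write_yield_map()]
#'
#' @param path Path to the `.tif` written by [write_yield_map()].
#' @return List with `values` (matrix, `NA` at nodata cells), `mask`,
#'   `cell_size_m`, `origin`.
#' @export
read_yield_map <- function(path) {
  if (!file.exists(path)) stop("no such raster: ", path, call. = FALSE)
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  packed <- tiff::readTIFF(path)
  mask <- packed != meta$nodata
  values <- matrix(NA_real_, nrow(packed), ncol(packed))
  values[mask] <- meta$value_min + (packed[mask] - 0.1) / 0.9 * meta$value_span
  list(values = values, mask = mask, cell_size_m = meta$cell_size_m,
       origin = as.numeric(meta$origin))
}
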