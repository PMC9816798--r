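#' Cloud-filtered monthly vegetation-index composites
#'
#' Computes the four vegetation indices per scene, discards every scene whose
#' cloud cover is strictly greater than `cloud_threshold` percent (a scene at
#' exactly the threshold is retained), averages the retained per-scene index
#' values within each month, and returns the per-sample index-by-month
#' matrix that feeds the regression models. Months left without any retained
#' scene are filled by linear interpolation between neighbouring months
#' (constant extrapolation at the season edges), keeping the model input
#' dense.
#'
#' @param series An [simulate_multispectral_series()] result (or any object
#'   with the same structure).
#' @param cloud_threshold Cloud-cover filter threshold in percent
#'   (default 30).
#' @return An object of class `vi_matrix`: list with `values` (array
#'   `samples x 4 indices x n_months`), `months`, `yield` (copied from the
#'   series if present) and `imputed_months` (integer vector of month steps
#'   that had no retained scene).
#' @examples
#' cfg <- scene_config(n_rows = 5, n_cols = 5, seed = 1)
#' vm <- monthly_composite(simulate_multispectral_series(generate_yield_grid(cfg)))
#' dim(vm$values)
#' @export
monthly_composite <- function(series, cloud_threshold = 30) {
  stopifnot(!is.null(series$reflectance), !is.null(series$scenes))
  scenes <- series$scenes
  keep <- scenes$cloud_fraction <= cloud_threshold   # strictly greater -> drop
  if (!any(keep)) {
    stop("no scene passes the ", cloud_threshold, "% cloud filter", call. = FALSE)
  }
  vi <- scene_vi_values(series)
  n <- dim(vi)[1]
  months <- unique(scenes$month)
  n_months <- max(scenes$month)

  values <- array(NA_real_, c(n, 4L, n_months),
                  dimnames = list(NULL, vi_names(),
                                  season_months(n_months)))
  for (m in seq_len(n_months)) {
    idx <- which(keep & scenes$month == m)
    if (length(idx) == 0L) next
    sl <- vi[, , idx, drop = FALSE]
    values[, , m] <- apply(sl, c(1, 2), mean, na.rm = TRUE)
  }
  values[is.nan(values)] <- NA_real_

  imputed <- integer(0)
  month_empty <- vapply(seq_len(n_months),
                        function(m) all(is.na(values[, , m])), logical(1))
  imputed <- which(month_empty)
  # fill gaps per sample x index along the month axis
  if (anyNA(values)) {
    for (k in seq_len(4L)) {
      sl <- matrix(values[, k, ], nrow = n)
      if (anyNA(sl)) {
        sl <- t(apply(sl, 1, function(v) {
          if (all(is.na(v))) return(v)
          zoo::na.approx(v, x = seq_along(v), na.rm = FALSE, rule = 2)
        }))
        values[, k, ] <- sl
      }
    }
  }

  structure(
    list(values = values, months = season_months(n_months),
         yield = series$yield, imputed_months = imputed),
    class = "vi_matrix"
  )
}

#' @export
print.vi_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vi_matrix> %d samples x %d indices x %d months\n",
              d[1], d[2], d[3]))
  if (length(x$imputed_months)) {
    cat("  imputed months:", paste(x$months[x$imputed_months], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten an index-by-month matrix into model feature vectors
#'
#' Row-major (index-major) flattening: all months of the first index, then
#' all months of the second, and so on. A 4-index, 9-month input becomes a
#' 36-length vector per sample; the 3-index, 4-date hyperspectral variant
#' becomes 12. The operation is inverted by [unflatten_vi_matrix()].
#'
#' @param m A `vi_matrix`, or a bare array `samples x indices x steps`.
#' @return Numeric matrix `samples x (indices * steps)` with names like
#'   `"SR_Apr"`.
#' @examples
#' a <- array(1:24, c(2, 3, 4), dimnames = list(NULL, c("A","B","C"), NULL))
#' dim(flatten_vi_matrix(a))
#' @export
flatten_vi_matrix <- function(m) {
  a <- if (inherits(m, "vi_matrix")) m$values else m
  stopifnot(length(dim(a)) == 3L)
  if (anyNA(a)) stop("matrix contains missing entries; impute first", call. = FALSE)
  d <- dim(a)
  vi <- dimnames(a)[[2]] %||% paste0("F", seq_len(d[2]))
  step <- dimnames(a)[[3]] %||% paste0("t", seq_len(d[3]))
  # index-major: columns ordered (vi1, t1..tK), (vi2, t1..tK), ...
  out <- matrix(aperm(a, c(1, 3, 2)), nrow = d[1])
  colnames(out) <- as.vector(outer(step, vi, function(s, v) paste(v, s, sep = "_")))
  out
}

#' Invert [flatten_vi_matrix()]
#'
#' @param flat Matrix `samples x (indices * steps)`.
#' @param n_vi,n_steps Shape of the original array.
#' @param vi,steps Optional dimension names.
#' @return Array `samples x n_vi x n_steps`.
#' @export
unflatten_vi_matrix <- function(flat, n_vi, n_steps, vi = NULL, steps = NULL) {
  stopifnot(ncol(flat) == n_vi * n_steps)
  a <- array(flat, c(nrow(flat), n_steps, n_vi))
  a <- aperm(a, c(1, 3, 2))
  dimnames(a) <- list(NULL, vi, steps)
  a
}

#' Arrange a `vi_matrix` as model-ready sequences
#'
#' Sequence models consume time-major inputs: `samples x months x indices`.
#'
#' @param m A `vi_matrix` or `samples x indices x steps` array.
#' @return Array `samples x steps x indices`.
#' @export
vi_matrix_to_sequences <- function(m) {
  a <- if (inherits(m, "vi_matrix")) m$values else m
  stopifnot(length(dim(a)) == 3L)
  aperm(a, c(1, 3, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
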