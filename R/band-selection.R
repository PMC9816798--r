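#' Two-band hyperspectral indices
#'
#' The three index families screened against yield, for any pair of band
#' reflectances `Ri`, `Rj`:
#'
#' * `SSI(i, j) = Ri - Rj` (simple difference);
#' * `RSI(i, j) = Ri / Rj` (ratio);
#' * `NDSI(i, j) = (Ri - Rj) / (Ri + Rj)` (normalized difference).
#'
#' Guard violations (`Rj <= 0` for RSI, `Ri + Rj <= 0` for NDSI) flag the
#' affected sample as `NA` rather than erroring.
#'
#' @param spectra Matrix `samples x bands` of reflectance (an
#'   [simulate_hyperspectral_samples()] `$spectra`, or any matrix).
#' @param i,j 1-based band column indices.
#' @param index_type One of `"SSI"`, `"RSI"`, `"NDSI"`.
#' @return Numeric vector, one index value per sample.
#' @examples
#' m <- rbind(c(0.3, 0.1), c(0.2, 0.4))
#' compute_pair_index(m, 1, 2, "NDSI")
#' @export
compute_pair_index <- function(spectra, i, j,
                               index_type = c("SSI", "RSI", "NDSI")) {
  index_type <- match.arg(index_type)
  if (inherits(spectra, "hs_table")) spectra <- spectra$spectra
  spectra <- as.matrix(spectra)
  stopifnot(i >= 1, j >= 1, i <= ncol(spectra), j <= ncol(spectra))
  ri <- spectra[, i]; rj <- spectra[, j]
  switch(index_type,
    SSI = ri - rj,
    RSI = { out <- ri / rj; out[rj <= 0] <- NA_real_; out },
    NDSI = { den <- ri + rj; out <- (ri - rj) / den; out[den <= 0] <- NA_real_; out }
  )
}

#' Correlation of every two-band index with yield
#'
#' Evaluates the chosen index family over all band pairs and computes the
#' Pearson correlation of each pair's index values with yield across
#' samples, plus a two-sided p-value from the t distribution. SSI and NDSI
#' are antisymmetric under band exchange, so their surfaces satisfy
#' `r(i, j) = -r(j, i)`; RSI is not symmetric and its full ordered surface
#' is kept. Pairs whose index is constant or undefined across samples are
#' flagged `NA`.
#'
#' @param table An `hs_table` (or a list with `spectra` and `yield`).
#' @param index_type One of `"SSI"`, `"RSI"`, `"NDSI"`.
#' @return An object of class `band_pair_surface`: list with `r` and `p`
#'   (`bands x bands` matrices, `NA` on the diagonal), `index_type`,
#'   `band_centers_nm`, and `n` (sample count).
#' @examples
#' tb <- simulate_hyperspectral_samples(config = scene_config(seed = 5))
#' surf <- pairwise_correlation_surface(tb, "NDSI")
#' range(surf$r, na.rm = TRUE)
#' @export
pairwise_correlation_surface <- function(table,
                                         index_type = c("SSI", "RSI", "NDSI")) {
  index_type <- match.arg(index_type)
  spectra <- as.matrix(table$spectra)
  y <- table$yield
  n <- nrow(spectra)
  if (n < 3L) stop("need at least 3 samples to correlate", call. = FALSE)
  b <- ncol(spectra)

  # vectorized over pairs: for each sample, the full bands x bands index
  # surface is an outer-product expression in the band values
  r <- matrix(NA_real_, b, b)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  corr_cols <- function(x) {
    # Pearson r of each column of x with y; NA for zero-variance columns
    xc <- sweep(x, 2, colMeans(x))
    sx <- sqrt(colSums(xc^2))
    out <- as.numeric(crossprod(xc, yc)) / (sx * sy)
    out[sx < 1e-12] <- NA_real_
    out
  }

  for (jj in seq_len(b)) {
    rj <- spectra[, jj]
    vals <- switch(index_type,
      SSI = spectra - rj,
      RSI = { v <- spectra / rj; v[rj <= 0, ] <- NA; v },
      NDSI = { den <- spectra + rj; v <- (spectra - rj) / den; v[den <= 0] <- NA; v })
    ok <- colSums(is.na(vals)) == 0
    rcol <- rep(NA_real_, b)
    if (any(ok)) rcol[ok] <- corr_cols(vals[, ok, drop = FALSE])
    r[, jj] <- rcol
  }
  diag(r) <- NA_real_

  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  structure(
    list(r = r, p = p, index_type = index_type,
         band_centers_nm = table$band_centers_nm %||% seq_len(b), n = n),
    class = "band_pair_surface"
  )
}

#' @export
print.band_pair_surface <- function(x, ...) {
  cat(sprintf("<band_pair_surface> %s, %d bands, n = %d samples\n",
              x$index_type, nrow(x$r), x$n))
  cat(sprintf("  r range: [%.3f, %.3f], %d unordered pairs\n",
              min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE),
              n_unordered_pairs(x)))
  invisible(x)
}

#' Count the evaluated unordered band pairs of a surface
#'
#' @param surface A [pairwise_correlation_surface()] result.
#' @return Integer: number of pairs `i < j` with a defined correlation.
#' @export
n_unordered_pairs <- function(surface) {
  sum(!is.na(surface$r[upper.tri(surface$r)]))
}

#' Heatmap of a band-pair correlation surface
#'
#' @param x A `band_pair_surface`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.band_pair_surface <- function(x, ...) {
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  graphics::image(x$band_centers_nm, x$band_centers_nm, x$r,
                  col = pal, zlim = c(-1, 1),
                  xlab = "band i (nm)", ylab = "band j (nm)",
                  main = paste0(x$index_type, " × yield correlation"), ...)
  invisible(x)
}

#' Select the extreme significant band pairs of a surface
#'
#' Returns the band pair with the largest and the pair with the smallest
#' (most negative) yield correlation among pairs passing the significance
#' filter `p < alpha`. For the antisymmetric families (SSI, NDSI) the search
#' runs over unordered pairs `i < j`; for RSI it runs over all ordered
#' pairs. Ties are broken toward the smaller `i`, then smaller `j`. If no
#' pair of a sign is significant that slot is `NULL` and a warning is
#' raised; a surface with no defined correlation at all is an error.
#'
#' @param surface A [pairwise_correlation_surface()] result.
#' @param alpha Significance level (default 0.001).
#' @param pairs `"auto"` (unordered for SSI/NDSI, ordered for RSI),
#'   `"unordered"`, or `"ordered"`.
#' @return An object of class `selection_result`: list with `index_type`,
#'   `positive` and `negative` (each `NULL` or a list `i`, `j`, `r`, `p`,
#'   `wavelength_i_nm`, `wavelength_j_nm`), and `alpha`.
#' @export
select_extreme_pairs <- function(surface, alpha = 0.001,
                                 pairs = c("auto", "unordered", "ordered")) {
  pairs <- match.arg(pairs)
  if (pairs == "auto") {
    pairs <- if (surface$index_type == "RSI") "ordered" else "unordered"
  }
  r <- surface$r; p <- surface$p
  if (all(is.na(r))) stop("surface has no defined correlations", call. = FALSE)
  cand <- if (pairs == "unordered") upper.tri(r) else row(r) != col(r)
  ok <- which(cand & !is.na(r) & p < alpha, arr.ind = TRUE)

  pick <- function(rows, decreasing) {
    if (nrow(rows) == 0L) return(NULL)
    rv <- r[rows]
    best <- if (decreasing) max(rv) else min(rv)
    at <- rows[abs(rv - best) < 1e-15, , drop = FALSE]
    at <- at[order(at[, 1], at[, 2]), , drop = FALSE]   # lexicographic tie-break
    i <- at[1, 1]; j <- at[1, 2]
    list(i = unname(i), j = unname(j), r = unname(r[i, j]), p = unname(p[i, j]),
         wavelength_i_nm = surface$band_centers_nm[i],
         wavelength_j_nm = surface$band_centers_nm[j])
  }

  pos <- pick(ok[r[ok] > 0, , drop = FALSE], decreasing = TRUE)
  neg <- pick(ok[r[ok] < 0, , drop = FALSE], decreasing = FALSE)
  if (is.null(pos)) warning("no significant positively correlated pair", call. = FALSE)
  if (is.null(neg)) warning("no significant negatively correlated pair", call. = FALSE)

  structure(list(index_type = surface$index_type, positive = pos,
                 negative = neg, alpha = alpha),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s (p < %g)\n", x$index_type, x$alpha))
  fmt <- function(s, lab) {
    if (is.null(s)) cat(sprintf("  %s: none significant\n", lab))
    else cat(sprintf("  %s: %.0f-%.0f nm, r = %.4f\n", lab,
                     s$wavelength_i_nm, s$wavelength_j_nm, s$r))
  }
  fmt(x$positive, "positive"); fmt(x$negative, "negative")
  invisible(x)
}

#' Run the full band screening for all three index families
#'
#' @param table An `hs_table`.
#' @param alpha Significance level.
#' @return Named list of [select_extreme_pairs()] results
#'   (`SSI`, `RSI`, `NDSI`), with the surfaces attached as
#'   `attr(, "surfaces")`.
#' @export
select_bands <- function(table, alpha = 0.001) {
  types <- c("SSI", "RSI", "NDSI")
  surfaces <- lapply(types, function(tp) pairwise_correlation_surface(table, tp))
  names(surfaces) <- types
  out <- lapply(surfaces, select_extreme_pairs, alpha = alpha)
  attr(out, "surfaces") <- surfaces
  out
}

# the pair with the largest |r| of a selection_result (used as the feature)
dominant_pair <- function(sel) {
  cands <- Filter(Negate(is.null), list(sel$positive, sel$negative))
  if (length(cands) == 0L) {
    stop("selection for ", sel$index_type, " is empty", call. = FALSE)
  }
  cands[[which.max(vapply(cands, function(s) abs(s$r), numeric(1)))]]
}

#' Extract the custom two-band features for the hyperspectral model
#'
#' For each index family, the band pair with the largest absolute yield
#' correlation in `selection` defines one feature; evaluating it on each
#' acquisition date gives the `3 x n_dates` per-sample input of the
#' hyperspectral model variant.
#'
#' @param tables A single `hs_table` or a named list of them (one per
#'   acquisition date, as from [simulate_hyperspectral_dates()]).
#' @param selection A [select_bands()] result (list of `selection_result`
#'   per index family).
#' @return Array `samples x 3 x n_dates` with dimnames
#'   `(NULL, c("SSI","RSI","NDSI"), dates)`.
#' @export
extract_custom_features <- function(tables, selection) {
  if (inherits(tables, "hs_table")) tables <- list(date1 = tables)
  types <- names(selection)
  n <- nrow(tables[[1]]$spectra)
  dates <- names(tables) %||% paste0("date", seq_along(tables))
  out <- array(NA_real_, c(n, length(types), length(tables)),
               dimnames = list(NULL, types, dates))
  for (tp in seq_along(types)) {
    pair <- dominant_pair(selection[[types[tp]]])
    for (d in seq_along(tables)) {
      out[, tp, d] <- compute_pair_index(tables[[d]]$spectra,
                                         pair$i, pair$j, types[tp])
    }
  }
  out
}
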