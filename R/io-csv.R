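# Plain-text round-trip IO for the pipeline artifacts. Every writer has a
# reader that reconstructs the object the downstream stage consumes.

#' Artifact readers and writers
#'
#' CSV/JSON serialization for the objects flowing between pipeline stages:
#' multispectral series (long CSV), index-by-month matrices (tidy and wide
#' CSV), hyperspectral tables (wide CSV with `nm_*` band columns),
#' band-pair surfaces (long CSV), selections (JSON) and scene configs
#' (JSON). Each `read_*` inverts the corresponding `write_*`.
#'
#' @param series,vm,table,surface,selection,config Object to write.
#' @param path File path.
#' @name artifact_io
NULL

#' @rdname artifact_io
#' @export
write_ms_series_csv <- function(series, path) {
  r <- series$reflectance
  d <- dim(r)
  long <- data.frame(
    sample = rep(seq_len(d[1]), times = d[2] * d[3]),
    band = rep(rep(dimnames(r)[[2]], each = d[1]), times = d[3]),
    scene = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(r)
  )
  long <- merge(long, series$scenes, by = "scene", sort = FALSE)
  long$yield <- series$yield[long$sample]
  utils::write.csv(long[, c("sample", "scene", "month", "cloud_fraction",
                            "band", "value", "yield")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_ms_series_csv <- function(path) {
  long <- utils::read.csv(path)
  bands <- multispectral_bands()
  samples <- sort(unique(long$sample))
  scenes <- sort(unique(long$scene))
  r <- array(NA_real_, c(length(samples), length(bands), length(scenes)),
             dimnames = list(NULL, bands, NULL))
  idx <- cbind(match(long$sample, samples), match(long$band, bands),
               match(long$scene, scenes))
  r[idx] <- long$value
  scene_info <- unique(long[, c("scene", "month", "cloud_fraction")])
  scene_info <- scene_info[order(scene_info$scene), ]
  rownames(scene_info) <- NULL
  yield <- long$yield[match(samples, long$sample)]
  structure(list(reflectance = r, scenes = scene_info, yield = yield,
                 months = season_months(max(scene_info$month)), config = NULL),
            class = "ms_series")
}

#' @rdname artifact_io
#' @export
write_vi_matrix_csv <- function(vm, path) {
  a <- vm$values
  d <- dim(a)
  tidy <- data.frame(
    sample = rep(seq_len(d[1]), times = d[2] * d[3]),
    vi = rep(rep(dimnames(a)[[2]], each = d[1]), times = d[3]),
    month = rep(dimnames(a)[[3]], each = d[1] * d[2]),
    value = as.vector(a)
  )
  if (!is.null(vm$yield)) tidy$yield <- vm$yield[tidy$sample]
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_vi_matrix_csv <- function(path) {
  tidy <- utils::read.csv(path)
  vis <- unique(tidy$vi); months <- unique(tidy$month)
  samples <- sort(unique(tidy$sample))
  a <- array(NA_real_, c(length(samples), length(vis), length(months)),
             dimnames = list(NULL, vis, months))
  a[cbind(match(tidy$sample, samples), match(tidy$vi, vis),
          match(tidy$month, months))] <- tidy$value
  yield <- if ("yield" %in% names(tidy)) tidy$yield[match(samples, tidy$sample)]
  structure(list(values = a, months = months, yield = yield,
                 imputed_months = integer(0)),
            class = "vi_matrix")
}

#' @rdname artifact_io
#' @export
write_hs_table_csv <- function(table, path) {
  df <- data.frame(sample = seq_len(nrow(table$spectra)),
                   yield = table$yield, table$spectra,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_hs_table_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  band_cols <- grep("^nm_", names(df), value = TRUE)
  spectra <- as.matrix(df[, band_cols])
  structure(list(spectra = spectra,
                 band_centers_nm = as.numeric(sub("^nm_", "", band_cols)),
                 yield = df$yield),
            class = "hs_table")
}

#' @rdname artifact_io
#' @export
write_surface_csv <- function(surface, path) {
  b <- length(surface$band_centers_nm)
  idx <- which(!is.na(surface$r), arr.ind = TRUE)
  long <- data.frame(
    i_nm = surface$band_centers_nm[idx[, 1]],
    j_nm = surface$band_centers_nm[idx[, 2]],
    index_type = surface$index_type,
    r = surface$r[idx], p = surface$p[idx]
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(selection, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' @rdname artifact_io
#' @export
write_scene_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname artifact_io
#' @export
read_scene_config_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lst$planted_pairs <- lapply(seq_len(nrow(lst$planted_pairs)), function(k) {
    as.list(lst$planted_pairs[k, ])
  })
  do.call(scene_config, lst)
}
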