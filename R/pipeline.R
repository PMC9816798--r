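#' Pipeline configuration
#'
#' Bundles the stage configurations and a single global seed from which each
#' stage derives its own seed by a fixed offset (simulation +0, split +100,
#' LSTM +200, importance +300), so stages are independently reproducible.
#'
#' @param scene A [scene_config()].
#' @param train_fraction Train share of the random split.
#' @param lstm An [lstm_config()].
#' @param models Character subset of `c("LSTM", "RF", "GBDT", "SVR")` to
#'   train.
#' @param alpha Band-selection significance level.
#' @param pfi_repeats Shuffles per feature in the importance stage.
#' @param clip_predictions Clamp predictions to the scene yield range.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(),
                            train_fraction = 0.9,
                            lstm = lstm_config(),
                            models = c("LSTM", "RF", "GBDT", "SVR"),
                            alpha = 0.001,
                            pfi_repeats = 10L,
                            clip_predictions = TRUE,
                            seed = 1L) {
  models <- match.arg(models, c("LSTM", "RF", "GBDT", "SVR"),
                      several.ok = TRUE)
  scene$seed <- as.integer(seed)
  lstm$seed <- as.integer(seed) + 200L
  structure(list(scene = validate_scene_config(scene),
                 train_fraction = train_fraction, lstm = lstm,
                 models = models, alpha = alpha,
                 pfi_repeats = as.integer(pfi_repeats),
                 clip_predictions = isTRUE(clip_predictions),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full yield-estimation pipeline
#'
#' Orchestrates all stages into one run directory: synthetic scene
#' generation, feature construction, train/test split, model fitting,
#' metric evaluation, permutation feature importance (on the LSTM when
#' trained, else the first model), management-factor summaries and a
#' predicted-yield map. Two variants are supported:
#'
#' * `"multispectral"` — 4 vegetation indices composited to monthly means
#'   (sequence input `months x 4`, flattened for the baselines);
#' * `"hyperspectral"` — the three custom two-band indices evaluated on each
#'   acquisition date (sequence input `dates x 3`), with the band screening
#'   fitted on a subset of `n_hyper_samples` calibration samples.
#'
#' @param config A [pipeline_config()].
#' @param variant `"multispectral"` or `"hyperspectral"`.
#' @param out_dir Run directory (created; contents overwritten).
#' @return Invisibly, a list with `metrics` (data.frame per model),
#'   `importance`, `management`, `models`, and `out_dir`.
#' @export
run_full_pipeline <- function(config, variant = c("multispectral",
                                                  "hyperspectral"),
                              out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  variant <- match.arg(variant)
  for (d in c("", "data", "features", "models", "reports", "maps")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  log_file <- file.path(out_dir, "pipeline.log")
  say <- function(stage, ...) {
    msg <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                   paste0(...))
    cat(msg, "\n", file = log_file, append = TRUE)
    message(msg)
  }
  run_stage <- function(stage, expr) {
    say(stage, "...")
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  jsonlite::write_json(resolve_config(config, variant),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  grid <- run_stage("simulate", {
    g <- generate_yield_grid(config$scene)
    write_yield_map(g, path = file.path(out_dir, "data", "yield_true.tif"))
    write_scene_config_json(config$scene,
                            file.path(out_dir, "data", "scene_config.json"))
    g
  })
  y <- grid_yields(grid)

  feats <- run_stage("features", {
    if (variant == "multispectral") {
      series <- simulate_multispectral_series(grid, config$scene)
      vm <- monthly_composite(series)
      write_vi_matrix_csv(vm, file.path(out_dir, "features", "vi_matrix.csv"))
      list(seq = vi_matrix_to_sequences(vm), flat = flatten_vi_matrix(vm))
    } else {
      dates_tables <- simulate_hyperspectral_dates(y, config$scene)
      calib <- seq_len(min(config$scene$n_hyper_samples, length(y)))
      calib_table <- structure(
        list(spectra = dates_tables[[1]]$spectra[calib, , drop = FALSE],
             band_centers_nm = dates_tables[[1]]$band_centers_nm,
             yield = y[calib]),
        class = "hs_table")
      write_hs_table_csv(calib_table,
                         file.path(out_dir, "data", "hyperspectral_calib.csv"))
      sel <- select_bands(calib_table, alpha = config$alpha)
      write_selection_json(sel, file.path(out_dir, "features", "selection.json"))
      for (tp in names(sel)) {
        write_surface_csv(attr(sel, "surfaces")[[tp]],
                          file.path(out_dir, "features",
                                    paste0("surface_", tolower(tp), ".csv")))
      }
      custom <- extract_custom_features(dates_tables, sel)
      list(seq = vi_matrix_to_sequences(custom),
           flat = flatten_vi_matrix(custom))
    }
  })

  split <- split_train_test(length(y), config$train_fraction,
                            seed = config$seed + 100L)
  clip <- if (config$clip_predictions) {
    c(config$scene$yield_min, config$scene$yield_max)
  }

  models <- list(); metrics <- list()
  for (kind in config$models) {
    fit <- run_stage(paste0("train-", kind), {
      if (kind == "LSTM") {
        train_lstm_regressor(feats$seq[split$train, , , drop = FALSE],
                             y[split$train], config$lstm)
      } else {
        train_baseline_regressor(feats$flat[split$train, , drop = FALSE],
                                 y[split$train], baseline_config(kind))
      }
    })
    models[[kind]] <- fit
    test_x <- if (kind == "LSTM") feats$seq[split$test, , , drop = FALSE]
              else feats$flat[split$test, , drop = FALSE]
    ev <- compute_metrics(y[split$test],
                          predict_yield(fit, test_x, clip = clip), "test")
    metrics[[kind]] <- data.frame(model = kind, mae = ev$mae,
                                  rmse = ev$rmse, r2 = ev$r2, m = ev$m)
    if (kind == "LSTM") {
      utils::write.csv(fit$log,
                       file.path(out_dir, "models", "lstm_training_log.csv"),
                       row.names = FALSE)
    }
    saveRDS(fit, file.path(out_dir, "models", paste0(tolower(kind), ".rds")))
    jsonlite::write_json(list(kind = kind, schema = fit$schema),
                         file.path(out_dir, "models",
                                   paste0(tolower(kind), "_schema.json")),
                         auto_unbox = TRUE, force = TRUE)
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  utils::write.csv(metrics, file.path(out_dir, "reports", "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "reports", "metrics.json"),
                       dataframe = "rows", digits = NA)

  pfi_model <- models[["LSTM"]] %||% models[[1]]
  importance <- run_stage("importance", {
    fx <- if (pfi_model$schema$type == "sequence") {
      feats$seq[split$test, , , drop = FALSE]
    } else feats$flat[split$test, , drop = FALSE]
    permutation_feature_importance(pfi_model, fx, y[split$test],
                                   n_repeats = config$pfi_repeats,
                                   seed = config$seed + 300L)
  })
  utils::write.csv(importance$importance,
                   file.path(out_dir, "reports", "importance.csv"),
                   row.names = FALSE)

  management <- run_stage("management", {
    tb <- generate_management_table(config$scene)
    utils::write.csv(tb, file.path(out_dir, "data", "management.csv"),
                     row.names = FALSE)
    summarize_management_effects(tb)
  })
  utils::write.csv(management,
                   file.path(out_dir, "reports", "management_summary.csv"),
                   row.names = FALSE)

  run_stage("map", {
    best <- models[[1]]
    full_x <- if (best$schema$type == "sequence") feats$seq else feats$flat
    pred <- predict_yield(best, full_x, clip = clip)
    write_yield_map(grid, pred, file.path(out_dir, "maps", "yield_pred.tif"))
    scatter <- data.frame(sample = split$test, y_true = y[split$test])
    test_x <- if (best$schema$type == "sequence") {
      feats$seq[split$test, , , drop = FALSE]
    } else feats$flat[split$test, , drop = FALSE]
    scatter$y_pred <- predict_yield(best, test_x, clip = clip)
    utils::write.csv(scatter,
                     file.path(out_dir, "reports", "scatter_test.csv"),
                     row.names = FALSE)
  })

  say("done", "variant=", variant, " models=",
      paste(config$models, collapse = ","))
  invisible(list(metrics = metrics, importance = importance,
                 management = management, models = models, out_dir = out_dir))
}

resolve_config <- function(config, variant = NULL) {
  out <- unclass(config)
  out$scene <- unclass(out$scene)
  out$lstm <- unclass(out$lstm)
  if (!is.null(variant)) out$variant <- variant
  out
}

#' Load a pipeline configuration from YAML
#'
#' The YAML file may define any subset of the [pipeline_config()] arguments;
#' `scene:` and `lstm:` sub-maps are passed to [scene_config()] and
#' [lstm_config()]. Omitted entries fall back to the defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path) %||% list()
  args <- raw
  args$scene <- do.call(scene_config, raw$scene %||% list())
  args$lstm <- do.call(lstm_config, raw$lstm %||% list())
  if (!is.null(seed)) args$seed <- seed
  args$models <- unlist(args$models %||% c("LSTM", "RF", "GBDT", "SVR"))
  do.call(pipeline_config, args)
}
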