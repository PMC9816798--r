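#' Regression accuracy metrics
#'
#' Mean absolute error, root mean squared error and the coefficient of
#' determination for yield predictions, in t/ha:
#' \deqn{MAE = \frac{1}{m} \sum_i |h(x_i) - y_i|}
#' \deqn{RMSE = \sqrt{\frac{1}{m} \sum_i (h(x_i) - y_i)^2}}
#' \deqn{R^2 = 1 - \sum_i (h(x_i) - y_i)^2 / \sum_i (y_i - \bar y)^2}
#' A zero-variance truth vector leaves `r2` as `NA` with a warning.
#'
#' @param y_true,y_pred Equal-length finite numeric vectors (t/ha).
#' @param split Label recorded in the report (e.g. `"test"`).
#' @return An object of class `evaluation_report`: list with `mae`, `rmse`,
#'   `r2`, `m` (sample count) and `split`.
#' @examples
#' compute_metrics(c(2, 4), c(3, 3))
#' @export
compute_metrics <- function(y_true, y_pred, split = "test") {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  err <- y_pred - y_true
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot < 1e-15) {
    warning("y_true has zero variance; R2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  structure(list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), r2 = r2,
                 m = length(y_true), split = split),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (m = %d)\n", x$split, x$m))
  cat(sprintf("  MAE %.4f t/ha | RMSE %.4f t/ha | R2 %s\n",
              x$mae, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2)))
  invisible(x)
}

#' Permutation feature importance
#'
#' Quantifies each feature's contribution to a fitted model by shuffling
#' that feature across samples — destroying its correspondence with yield
#' while preserving its marginal distribution — and recomputing the
#' prediction loss without retraining. For sequence inputs the whole
#' temporal trajectory of a feature is permuted as a unit, so within-sample
#' temporal structure is preserved; for flattened inputs all columns
#' belonging to a feature are permuted jointly with one permutation. The
#' shuffle is repeated `n_repeats` times and the mean loss reported;
#' features are ranked by descending shuffled loss.
#'
#' @param model A fitted `yield_model`.
#' @param features Model-schema features (sequence array or flat matrix).
#' @param y_true True yields (t/ha).
#' @param n_repeats Number of independent shuffles per feature.
#' @param seed RNG seed.
#' @param loss `"mse"` (default) or `"rmse"`.
#' @param groups For flat features only: integer or factor of length
#'   `ncol(features)` mapping columns to features. Defaults to grouping by
#'   the column-name prefix before `"_"` (the [flatten_vi_matrix()]
#'   convention), or one group per column if names are absent.
#' @return An object of class `importance_report`: list with `importance`
#'   (data.frame `feature`, `loss`, `rank`), `baseline_loss`, `loss_type`,
#'   `n_repeats`, `seed`.
#' @export
permutation_feature_importance <- function(model, features, y_true,
                                           n_repeats = 10, seed = 1L,
                                           loss = c("mse", "rmse"),
                                           groups = NULL) {
  loss <- match.arg(loss)
  loss_fn <- function(yt, yp) {
    v <- mean((yp - yt)^2)
    if (loss == "rmse") sqrt(v) else v
  }
  seq_input <- length(dim(features)) == 3L
  n <- dim(features)[1]
  if (n < 2L) stop("need at least 2 samples to permute", call. = FALSE)

  if (seq_input) {
    f_names <- dimnames(features)[[3]] %||% paste0("F", seq_len(dim(features)[3]))
    n_feat <- dim(features)[3]
  } else {
    features <- as.matrix(features)
    if (is.null(groups)) {
      cn <- colnames(features)
      groups <- if (is.null(cn)) seq_len(ncol(features)) else sub("_.*$", "", cn)
    }
    groups <- factor(groups, levels = unique(groups))
    f_names <- levels(groups)
    n_feat <- nlevels(groups)
  }

  baseline <- loss_fn(y_true, predict_yield(model, features))
  set.seed(as.integer(seed))
  losses <- matrix(NA_real_, n_repeats, n_feat,
                   dimnames = list(NULL, f_names))
  for (r in seq_len(n_repeats)) {
    for (k in seq_len(n_feat)) {
      perm <- sample.int(n)
      shuffled <- features
      if (seq_input) {
        shuffled[, , k] <- features[perm, , k]
      } else {
        cols <- which(as.integer(groups) == k)
        shuffled[, cols] <- features[perm, cols, drop = FALSE]
      }
      losses[r, k] <- loss_fn(y_true, predict_yield(model, shuffled))
    }
  }
  mean_loss <- colMeans(losses)
  imp <- data.frame(feature = f_names, loss = unname(mean_loss))
  imp$rank <- rank(-imp$loss, ties.method = "first")
  imp <- imp[order(imp$rank), ]
  rownames(imp) <- NULL

  structure(list(importance = imp, baseline_loss = baseline,
                 loss_type = loss, n_repeats = n_repeats, seed = seed),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %s loss, baseline %.4f, %d repeat(s)\n",
              x$loss_type, x$baseline_loss, x$n_repeats))
  print(x$importance, row.names = FALSE)
  invisible(x)
}

#' Group yields by planting-management factors
#'
#' Per-level mean, standard deviation and sample count for each management
#' factor in the table (seeding rate, tillage, fertilization mode,
#' irrigation). Levels with fewer than two samples are omitted with a
#' warning.
#'
#' @param table A [generate_management_table()] data.frame (columns
#'   `seeding_rate`, `tillage`, `fertilizer`, `irrigation_mm`, `yield`).
#' @param factors Factor columns to summarize.
#' @return Long `data.frame` with columns `factor`, `level`, `mean`, `sd`,
#'   `n`, ordered by factor then level.
#' @export
summarize_management_effects <- function(table,
                                         factors = c("seeding_rate", "tillage",
                                                     "fertilizer",
                                                     "irrigation_mm")) {
  stopifnot("yield" %in% names(table), all(factors %in% names(table)))
  out <- do.call(rbind, lapply(factors, function(f) {
    lev <- table[[f]]
    agg <- do.call(rbind, lapply(split(table$yield, lev, drop = TRUE),
                                 function(v) {
      data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
    }))
    agg <- data.frame(factor = f, level = rownames(agg), agg, row.names = NULL)
    small <- agg$n < 2
    if (any(small)) {
      warning("omitting level(s) with < 2 samples in '", f, "': ",
              paste(agg$level[small], collapse = ", "), call. = FALSE)
      agg <- agg[!small, ]
    }
    agg
  }))
  rownames(out) <- NULL
  out
}
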