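# Adam update; state holds m and v mirrors of the parameter structure
adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (l in seq_along(par$layers)) {
    for (nm in c("Wx", "Wh", "b")) {
      u <- upd(par$layers[[l]][[nm]], grad$layers[[l]][[nm]],
               state$layers[[l]][[nm]]$m, state$layers[[l]][[nm]]$v)
      par$layers[[l]][[nm]] <- u$p
      state$layers[[l]][[nm]] <- list(m = u$m, v = u$v)
    }
  }
  for (nm in c("w", "b0")) {
    u <- upd(par$head[[nm]], grad$head[[nm]],
             state$head[[nm]]$m, state$head[[nm]]$v)
    par$head[[nm]] <- u$p
    state$head[[nm]] <- list(m = u$m, v = u$v)
  }
  list(par = par, state = state)
}

init_adam_state <- function(par) {
  zero_like <- function(p) list(m = p * 0, v = p * 0)
  list(layers = lapply(par$layers, function(l) lapply(l, zero_like)),
       head = lapply(par$head, zero_like))
}

#' Train the LSTM yield regressor
#'
#' Fits a stacked-LSTM sequence-to-scalar regressor by minibatch Adam on the
#' mean-squared-error loss with L2 weight regularization and inverted
#' dropout on each layer's outputs. Features and target are z-scored on the
#' training data (stored in the model and inverted at prediction). Training
#' runs a fixed number of epochs without early stopping; a non-finite loss
#' aborts with a diagnostic.
#'
#' @param x Array `samples x timesteps x features` (time-major sequences;
#'   see [vi_matrix_to_sequences()]).
#' @param y Yield vector (t/ha), one per sample.
#' @param config An [lstm_config()].
#' @return A `yield_model` of kind `"LSTM"` with the fitted parameters,
#'   the feature schema and a training log (`data.frame(epoch, loss)`).
#' @examples
#' sim <- simulate_vi_sequences(40, seed = 1)
#' m <- train_lstm_regressor(sim$x, sim$y,
#'                           lstm_config(hidden_units = 8, epochs = 3))
#' head(predict_yield(m, sim$x))
#' @export
train_lstm_regressor <- function(x, y, config = lstm_config()) {
  stopifnot(inherits(config, "lstm_config"), length(dim(x)) == 3L,
            dim(x)[1] == length(y))
  n <- dim(x)[1]; TT <- dim(x)[2]; FF <- dim(x)[3]
  set.seed(config$seed)

  if (config$standardize) {
    x_center <- apply(x, 3, mean); x_scale <- apply(x, 3, stats::sd)
    x_scale[x_scale < 1e-12] <- 1
    y_center <- mean(y); y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  } else {
    x_center <- rep(0, FF); x_scale <- rep(1, FF); y_center <- 0; y_scale <- 1
  }
  xs <- standardize_sequences(x, x_center, x_scale)
  ys <- (y - y_center) / y_scale

  params <- init_lstm_params(FF, config)
  state <- init_adam_state(params)
  keep <- 1 - config$dropout
  H <- config$hidden_units
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  step <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      nb <- length(idx)
      xb <- xs[idx, , , drop = FALSE]
      masks <- NULL
      if (config$dropout > 0) {
        masks <- lapply(seq_len(config$n_layers), function(l) {
          matrix((stats::runif(nb * H) < keep) / keep, nb, H)
        })
      }
      lg <- lstm_loss_grads(params, xb, ys[idx], l2 = config$l2_lambda,
                            masks = masks)
      if (!is.finite(lg$loss)) {
        stop("LSTM training diverged (non-finite loss at epoch ", epoch,
             "); lower the learning rate or noise", call. = FALSE)
      }
      step <- step + 1L
      ad <- adam_step(params, lg$grads, state, config$learning_rate, step)
      params <- ad$par; state <- ad$state
      batch_losses <- c(batch_losses, lg$mse)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = mean(batch_losses)))
  }

  structure(
    list(kind = "LSTM", params = params, config = config,
         schema = list(type = "sequence", timesteps = TT, features = FF,
                       feature_names = dimnames(x)[[3]]),
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         log = log),
    class = "yield_model"
  )
}

standardize_sequences <- function(x, center, scale) {
  for (k in seq_len(dim(x)[3])) {
    x[, , k] <- (x[, , k] - center[k]) / scale[k]
  }
  x
}

predict_lstm <- function(model, x) {
  xs <- standardize_sequences(x, model$x_center, model$x_scale)
  fw <- lstm_forward(model$params, xs, masks = NULL)
  fw$pred * model$y_scale + model$y_center
}
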