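#' LSTM training configuration
#'
#' Hyperparameters of the sequence regressor: a stack of LSTM layers whose
#' final hidden state passes through a ReLU and a fully connected head to a
#' single yield value. Defaults follow the reference experiment: two layers
#' of 100 units, dropout 0.3, L2 regularization, Adam at learning rate
#' 0.001, batch size 64, 700 epochs, mean-squared-error loss.
#'
#' @param n_layers Number of stacked LSTM layers.
#' @param hidden_units Hidden state size per layer.
#' @param dropout Dropout rate applied to each layer's output during
#'   training (inverted dropout), in `[0, 1)`.
#' @param l2_lambda L2 penalty coefficient on all weight matrices (biases
#'   excluded).
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (no early stopping).
#' @param standardize Z-score features and target on training statistics.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(n_layers = 2L, hidden_units = 100L, dropout = 0.3,
                        l2_lambda = 1e-4, learning_rate = 0.001,
                        batch_size = 64L, epochs = 700L,
                        standardize = TRUE, seed = 1L) {
  stopifnot(n_layers >= 1, hidden_units >= 1, dropout >= 0, dropout < 1,
            l2_lambda >= 0, learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units),
                 dropout = dropout, l2_lambda = l2_lambda,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "lstm_config")
}

#' One step of an LSTM cell, in the gate-equation form
#'
#' Evaluates the canonical LSTM cell update for a single time step:
#' \deqn{i_t = \sigma(W_{ih} h_{t-1} + W_{ix} x_t + b_i)}
#' \deqn{f_t = \sigma(W_{fh} h_{t-1} + W_{fx} x_t + b_f)}
#' \deqn{g_t = \tanh(W_{gh} h_{t-1} + W_{gx} x_t + b_g)}
#' \deqn{c_t = i_t \otimes g_t + f_t \otimes c_{t-1}}
#' \deqn{o_t = \sigma(W_{oh} h_{t-1} + W_{ox} x_t + b_o)}
#' \deqn{h_t = o_t \otimes \tanh(c_t)}
#' where \eqn{\sigma} is the logistic function and \eqn{\otimes} the
#' element-wise product. This is the semantic contract of the training code;
#' the vectorized trainer is tested against it.
#'
#' @param x Input vector at time t (length F).
#' @param h_prev,c_prev Previous hidden and cell state (length H).
#' @param weights List with `W_ih`, `W_fh`, `W_gh`, `W_oh` (H x H), `W_ix`,
#'   `W_fx`, `W_gx`, `W_ox` (H x F), and `b_i`, `b_f`, `b_g`, `b_o`
#'   (length H).
#' @return List with gates `i`, `f`, `g`, `o` and states `c`, `h`.
#' @export
lstm_cell_step <- function(x, h_prev, c_prev, weights) {
  w <- weights
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(as.numeric(w$W_ih %*% h_prev + w$W_ix %*% x + w$b_i))
  f <- sg(as.numeric(w$W_fh %*% h_prev + w$W_fx %*% x + w$b_f))
  g <- tanh(as.numeric(w$W_gh %*% h_prev + w$W_gx %*% x + w$b_g))
  o <- sg(as.numeric(w$W_oh %*% h_prev + w$W_ox %*% x + w$b_o))
  c_t <- i * g + f * c_prev
  h_t <- o * tanh(c_t)
  list(i = i, f = f, g = g, o = o, c = c_t, h = h_t)
}

# ---- internal vectorized LSTM -------------------------------------------
# Parameters per layer: Wx (F_in x 4H), Wh (H x 4H), b (4H), gate column
# blocks ordered i, f, g, o. Head: w (H), b0 (scalar).

sigmoid <- function(z) 1 / (1 + exp(-z))

init_lstm_params <- function(n_features, config) {
  H <- config$hidden_units
  lim <- 1 / sqrt(H)
  layer <- function(f_in) {
    list(Wx = matrix(stats::runif(f_in * 4 * H, -lim, lim), f_in, 4 * H),
         Wh = matrix(stats::runif(H * 4 * H, -lim, lim), H, 4 * H),
         b = rep(0, 4 * H))
  }
  layers <- vector("list", config$n_layers)
  f_in <- n_features
  for (l in seq_len(config$n_layers)) {
    layers[[l]] <- layer(f_in)
    f_in <- H
  }
  list(layers = layers,
       head = list(w = matrix(stats::runif(H, -lim, lim), H, 1), b0 = 0))
}

# forward pass of one layer over X (n x T x F); returns outputs and cache
lstm_layer_forward <- function(par, X) {
  n <- dim(X)[1]; TT <- dim(X)[2]
  H <- nrow(par$Wh)
  gi <- 1:H; gf <- H + gi; gg <- 2 * H + gi; go <- 3 * H + gi
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  Hout <- array(0, c(n, TT, H))
  cache <- vector("list", TT)
  for (t in seq_len(TT)) {
    xt <- matrix(X[, t, ], nrow = n)
    a <- xt %*% par$Wx + h %*% par$Wh
    a <- sweep(a, 2, par$b, `+`)
    i <- sigmoid(a[, gi, drop = FALSE]); f <- sigmoid(a[, gf, drop = FALSE])
    g <- tanh(a[, gg, drop = FALSE]); o <- sigmoid(a[, go, drop = FALSE])
    c_prev <- cc
    cc <- i * g + f * c_prev
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    Hout[, t, ] <- h
    cache[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                       i = i, f = f, g = g, o = o, tc = tc)
  }
  list(H = Hout, cache = cache)
}

# backward pass of one layer; dH: n x T x H gradient wrt layer outputs
lstm_layer_backward <- function(par, cache, dH) {
  n <- dim(dH)[1]; TT <- dim(dH)[2]; H <- dim(dH)[3]
  f_in <- nrow(par$Wx)
  dWx <- matrix(0, f_in, 4 * H); dWh <- matrix(0, nrow(par$Wh), 4 * H)
  db <- rep(0, 4 * H)
  dX <- array(0, c(n, TT, f_in))
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(TT))) {
    cc <- cache[[t]]
    dh <- matrix(dH[, t, ], nrow = n) + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dc_next <- dc * cc$f
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, da)
    dWh <- dWh + crossprod(cc$h_prev, da)
    db <- db + colSums(da)
    dX[, t, ] <- da %*% t(par$Wx)
    dh_next <- da %*% t(par$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# full forward; dropout masks (list per layer of n x H matrices or NULL)
lstm_forward <- function(params, X, masks = NULL) {
  n <- dim(X)[1]; TT <- dim(X)[2]
  inp <- X
  layer_out <- vector("list", length(params$layers))
  for (l in seq_along(params$layers)) {
    fw <- lstm_layer_forward(params$layers[[l]], inp)
    Hd <- fw$H
    if (!is.null(masks) && !is.null(masks[[l]])) {
      for (t in seq_len(TT)) Hd[, t, ] <- Hd[, t, ] * masks[[l]]
    }
    layer_out[[l]] <- list(fw = fw, H_dropped = Hd)
    inp <- Hd
  }
  H_last <- layer_out[[length(params$layers)]]$H_dropped
  hT <- matrix(H_last[, TT, ], nrow = n)
  relu <- pmax(hT, 0)
  pred <- as.numeric(relu %*% params$head$w + params$head$b0)
  list(pred = pred, layer_out = layer_out, hT = hT, relu = relu)
}

# loss + gradients for a batch; returns list(loss, grads) with grads
# mirroring the params structure. l2 applies to Wx, Wh and head w.
lstm_loss_grads <- function(params, X, y, l2 = 0, masks = NULL) {
  n <- dim(X)[1]; TT <- dim(X)[2]
  fw <- lstm_forward(params, X, masks)
  err <- fw$pred - y
  mse <- mean(err^2)
  l2_terms <- sum(vapply(params$layers,
                         function(p) sum(p$Wx^2) + sum(p$Wh^2), numeric(1))) +
    sum(params$head$w^2)
  loss <- mse + l2 / 2 * l2_terms

  dpred <- matrix(2 * err / n, ncol = 1)
  dw <- crossprod(fw$relu, dpred) + l2 * params$head$w
  db0 <- sum(dpred)
  dhT <- (dpred %*% t(params$head$w)) * (fw$hT > 0)

  n_layers <- length(params$layers)
  grads <- list(layers = vector("list", n_layers),
                head = list(w = dw, b0 = db0))
  H <- ncol(dhT)
  dH <- array(0, c(n, TT, H))
  dH[, TT, ] <- dhT
  for (l in rev(seq_len(n_layers))) {
    if (!is.null(masks) && !is.null(masks[[l]])) {
      for (t in seq_len(TT)) dH[, t, ] <- dH[, t, ] * masks[[l]]
    }
    bw <- lstm_layer_backward(params$layers[[l]], fw$layer_out[[l]]$fw$cache, dH)
    grads$layers[[l]] <- list(Wx = bw$dWx + l2 * params$layers[[l]]$Wx,
                              Wh = bw$dWh + l2 * params$layers[[l]]$Wh,
                              b = bw$db)
    dH <- bw$dX
  }
  list(loss = loss, mse = mse, grads = grads)
}
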