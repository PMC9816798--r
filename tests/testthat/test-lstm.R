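test_that("the cell step reproduces the gate equations evaluated by hand", {
  set.seed(61)
  H <- 3; F <- 2
  w <- list(
    W_ih = matrix(rnorm(H * H), H), W_ix = matrix(rnorm(H * F), H),
    b_i = rnorm(H),
    W_fh = matrix(rnorm(H * H), H), W_fx = matrix(rnorm(H * F), H),
    b_f = rnorm(H),
    W_gh = matrix(rnorm(H * H), H), W_gx = matrix(rnorm(H * F), H),
    b_g = rnorm(H),
    W_oh = matrix(rnorm(H * H), H), W_ox = matrix(rnorm(H * F), H),
    b_o = rnorm(H))
  x <- c(0.4, -1.2); h0 <- c(0.1, -0.3, 0.5); c0 <- c(0.2, 0.0, -0.4)

  step <- lstm_cell_step(x, h0, c0, w)

  sig <- function(z) 1 / (1 + exp(-z))   # independent hand evaluation
  i <- sig(w$W_ih %*% h0 + w$W_ix %*% x + w$b_i)
  f <- sig(w$W_fh %*% h0 + w$W_fx %*% x + w$b_f)
  g <- tanh(w$W_gh %*% h0 + w$W_gx %*% x + w$b_g)
  o <- sig(w$W_oh %*% h0 + w$W_ox %*% x + w$b_o)
  c1 <- i * g + f * c0
  h1 <- o * tanh(c1)

  expect_equal(step$c, as.numeric(c1), tolerance = 1e-6)
  expect_equal(step$h, as.numeric(h1), tolerance = 1e-6)
  expect_equal(step$i, as.numeric(i), tolerance = 1e-6)
  expect_equal(step$f, as.numeric(f), tolerance = 1e-6)
  expect_equal(step$o, as.numeric(o), tolerance = 1e-6)
})

test_that("the vectorized layer forward agrees with repeated cell steps", {
  set.seed(62)
  FF <- 2; H <- 4; TT <- 3
  cfg <- lstm_config(n_layers = 1, hidden_units = H, dropout = 0, seed = 62)
  params <- wheatyield:::init_lstm_params(FF, cfg)
  X <- array(rnorm(1 * TT * FF), c(1, TT, FF))
  fw <- wheatyield:::lstm_layer_forward(params$layers[[1]], X)

  # translate the packed (Wx, Wh, b) layout into per-gate matrices
  Wx <- params$layers[[1]]$Wx; Wh <- params$layers[[1]]$Wh
  b <- params$layers[[1]]$b
  blk <- function(k) ((k - 1) * H + 1):(k * H)
  w <- list(W_ih = t(Wh[, blk(1)]), W_ix = t(Wx[, blk(1)]), b_i = b[blk(1)],
            W_fh = t(Wh[, blk(2)]), W_fx = t(Wx[, blk(2)]), b_f = b[blk(2)],
            W_gh = t(Wh[, blk(3)]), W_gx = t(Wx[, blk(3)]), b_g = b[blk(3)],
            W_oh = t(Wh[, blk(4)]), W_ox = t(Wx[, blk(4)]), b_o = b[blk(4)])
  h <- rep(0, H); cc <- rep(0, H)
  for (t in 1:TT) {
    st <- lstm_cell_step(X[1, t, ], h, cc, w)
    h <- st$h; cc <- st$c
    expect_equal(as.numeric(fw$H[1, t, ]), h, tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(63)
  n <- 4; TT <- 3; FF <- 2; H <- 3
  cfg <- lstm_config(n_layers = 2, hidden_units = H, dropout = 0,
                     l2_lambda = 0.01, seed = 63)
  params <- wheatyield:::init_lstm_params(FF, cfg)
  X <- array(rnorm(n * TT * FF), c(n, TT, FF))
  y <- rnorm(n)
  lg <- wheatyield:::lstm_loss_grads(params, X, y, l2 = 0.01)
  eps <- 1e-6
  check <- function(get, set, ga) {
    p <- get(params)
    ks <- sample(seq_along(p), min(6, length(p)))   # spot-check entries
    for (k in ks) {
      pp <- p; pp[k] <- p[k] + eps
      l1 <- wheatyield:::lstm_loss_grads(set(params, pp), X, y, l2 = 0.01)$loss
      pp[k] <- p[k] - eps
      l2v <- wheatyield:::lstm_loss_grads(set(params, pp), X, y, l2 = 0.01)$loss
      expect_equal(ga[k], (l1 - l2v) / (2 * eps), tolerance = 1e-5)
    }
  }
  for (l in 1:2) for (nm in c("Wx", "Wh", "b")) {
    check(function(p) p$layers[[l]][[nm]],
          function(p, v) { p$layers[[l]][[nm]][] <- v; p },
          lg$grads$layers[[l]][[nm]])
  }
  check(function(p) p$head$w, function(p, v) { p$head$w[] <- v; p },
        lg$grads$head$w)
})

test_that("training is seed-reproducible and fits a noiseless linear target", {
  set.seed(64)
  n <- 60; TT <- 5; FF <- 2
  X <- array(runif(n * TT * FF), c(n, TT, FF))
  y <- 2 + 3 * apply(X[, , 1], 1, mean)   # linear in feature 1, no noise
  cfg <- lstm_config(n_layers = 2, hidden_units = 16, dropout = 0,
                     epochs = 150, batch_size = 16, seed = 64)
  m1 <- train_lstm_regressor(X, y, cfg)
  m2 <- train_lstm_regressor(X, y, cfg)
  expect_identical(m1$params, m2$params)

  pred <- predict_yield(m1, X)
  expect_lt(sqrt(mean((pred - y)^2)), 0.08)
  # loss decreased over training
  expect_lt(tail(m1$log$loss, 1), m1$log$loss[1])
})

test_that("constant targets are predicted near the constant", {
  set.seed(65)
  X <- array(rnorm(40 * 4 * 3), c(40, 4, 3))
  y <- rep(4.2, 40)
  m <- train_lstm_regressor(X, y, lstm_config(hidden_units = 8, epochs = 30,
                                              dropout = 0, seed = 65))
  expect_true(all(abs(predict_yield(m, X) - 4.2) < 0.2))
})
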