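# Small shared fixtures; everything is generated in code at test time.

tiny_config <- function(seed = 1L, ...) {
  scene_config(n_rows = 6, n_cols = 6, seed = seed, ...)
}

# a hyperspectral config carrying a single planted pair
single_pair_config <- function(seed = 1L, i = 120L, j = 140L, sign = +1,
                               noise_sd = 0.005) {
  scene_config(seed = seed, noise_sd = noise_sd,
               planted_pairs = list(list(i = i, j = j, sign = sign)))
}

# minutes-long stages use this reduced-but-faithful LSTM setting
fast_lstm <- function(epochs = 25L, seed = 1L, ...) {
  lstm_config(epochs = epochs, seed = seed, ...)
}

# direct-arithmetic oracles, written independently of the package internals
oracle_evi <- function(b2, b4, b8) 2.5 * (b8 - b4) / (b8 + 6 * b4 - 7.5 * b2 + 1)
oracle_sr <- function(b4, b8) b8 / b4
oracle_ndwi <- function(b8, b11) (b8 - b11) / (b8 + b11)
oracle_rep <- function(b4, b5, b6, b7) 705 + 35 * (0.5 * (b4 + b7) - b5) / (b6 - b5)
oracle_ssi <- function(ri, rj) ri - rj
oracle_rsi <- function(ri, rj) ri / rj
oracle_ndsi <- function(ri, rj) (ri - rj) / (ri + rj)
oracle_mae <- function(yt, yp) sum(abs(yp - yt)) / length(yt)
oracle_rmse <- function(yt, yp) sqrt(sum((yp - yt)^2) / length(yt))
oracle_r2 <- function(yt, yp) 1 - sum((yp - yt)^2) / sum((yt - mean(yt))^2)
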