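test_that("metrics match hand arithmetic and known identities", {
  r <- compute_metrics(c(2, 4), c(3, 3))
  expect_equal(r$mae, 1)
  expect_equal(r$rmse, 1)
  expect_equal(r$r2, 0)
  expect_equal(r$m, 2L)

  y <- c(1.5, 3.2, 4.8, 6.1)
  perfect <- compute_metrics(y, y)
  expect_equal(c(perfect$mae, perfect$rmse, perfect$r2), c(0, 0, 1))

  null_model <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(null_model$r2, 0)

  expect_warning(flat <- compute_metrics(rep(2, 3), c(1, 2, 3)), "zero variance")
  expect_true(is.na(flat$r2))
})

test_that("metrics match the oracle and RMSE >= MAE on random cases", {
  set.seed(81)
  for (k in 1:50) {
    n <- sample(2:40, 1)
    yt <- rnorm(n, 4, 1.5)
    yp <- yt + rnorm(n, sd = runif(1, 0, 2))
    r <- compute_metrics(yt, yp)
    expect_equal(r$mae, oracle_mae(yt, yp))
    expect_equal(r$rmse, oracle_rmse(yt, yp))
    expect_equal(r$r2, oracle_r2(yt, yp))
    expect_gte(r$rmse, r$mae)
    # R2 identity through the RMSE
    expect_equal(r$r2, 1 - n * r$rmse^2 / sum((yt - mean(yt))^2))
  }
})

test_that("permutation importance ranks features and spares irrelevant ones", {
  set.seed(82)
  n <- 150
  x <- matrix(rnorm(n * 6), n)
  colnames(x) <- paste0(rep(c("A", "B", "C"), each = 2), "_", 1:2)
  y <- 3 * x[, 1] + 3 * x[, 2] + rnorm(n, sd = 0.1)   # only feature A matters
  m <- train_baseline_regressor(x, y, baseline_config("RF", n_trees = 150))
  imp <- permutation_feature_importance(m, x, y, n_repeats = 5, seed = 3)

  expect_setequal(imp$importance$rank, 1:3)
  expect_equal(imp$importance$feature[imp$importance$rank == 1], "A")
  # shuffling features the model ignores barely moves the loss
  idle <- imp$importance$loss[imp$importance$feature != "A"]
  expect_true(all(idle < imp$baseline_loss * 3 + 0.3))
  expect_gt(imp$importance$loss[imp$importance$feature == "A"],
            10 * imp$baseline_loss)
})

test_that("sequence-model importance permutes whole trajectories", {
  set.seed(83)
  sim <- simulate_vi_sequences(100, dominant = 3, seed = 17)
  m <- train_lstm_regressor(sim$x, sim$y,
                            lstm_config(hidden_units = 16, epochs = 40,
                                        dropout = 0, batch_size = 32, seed = 5))
  imp <- permutation_feature_importance(m, sim$x, sim$y, n_repeats = 3, seed = 7)
  expect_equal(imp$importance$feature[imp$importance$rank == 1], "VI3")
  expect_error(
    permutation_feature_importance(m, sim$x[1, , , drop = FALSE], sim$y[1]),
    "at least 2")
})

test_that("management summaries behave on degenerate tables", {
  tb <- data.frame(
    seeding_rate = rep(c(150, 225), each = 4),
    tillage = factor(rep(c("Tillage", "Rotatillage"), 4)),
    fertilizer = factor(rep(c("constant", "variable"), 4)),
    irrigation_mm = rep(c(0, 60), 4),
    yield = rep(4, 8))
  sm <- summarize_management_effects(tb)
  expect_true(all(sm$mean == 4))
  expect_true(all(sm$sd == 0))

  tb2 <- tb
  tb2$tillage <- factor(c("Tillage", rep("Rotatillage", 7)),
                        levels = c("Tillage", "Rotatillage"))
  expect_warning(sm2 <- summarize_management_effects(tb2), "omitting")
  expect_false("Tillage" %in% sm2$level[sm2$factor == "tillage"])
})
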