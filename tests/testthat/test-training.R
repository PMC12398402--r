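test_that("loss strategies reproduce hand-computed cross-entropies", {
  # y_T = 0.5, label 1 -> ln 2
  expect_equal(loss_s1(matrix(0.5, 1, 3), 1), log(2), tolerance = 1e-12)
  # perfect fit limit
  expect_lt(loss_s1(matrix(c(0.5, 0.5, 1 - 1e-9), 1, 3), 1), 1e-8)
  # batch of two trials: mean of -ln 0.9 twice
  expect_equal(loss_s1(matrix(c(0.9, 0.1), 2, 1), c(1, 0)), -log(0.9),
               tolerance = 1e-12)
  # constant 0.5 -> ln 2 regardless of T
  expect_equal(loss_s2(matrix(0.5, 2, 7), c(1, 0)), log(2), tolerance = 1e-12)
  # T = 1 reduces to the final-step loss
  m <- matrix(c(0.3, 0.8), 2, 1)
  expect_identical(loss_s2(m, c(0, 1)), loss_s1(m, c(0, 1)))
  # T = 3 hand computation
  expect_equal(loss_s2(matrix(c(0.5, 0.9, 0.9), 1, 3), 1),
               mean(-log(c(0.5, 0.9, 0.9))), tolerance = 1e-12)
})

test_that("cross-validation splits partition trials with stratified sizes", {
  sp <- make_cv_splits(100, rep(0:1, 50), K = 5, validation_rate = 0.2,
                       seed = 1)
  for (f in sp$folds) {
    expect_length(f$test, 20L)
    expect_length(f$validation, 16L)
    expect_length(f$train, 64L)
    expect_length(intersect(f$train, f$validation), 0L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$validation, f$test), 0L)
    # stratification: both roles see both classes at the right rate
    expect_equal(sum(rep(0:1, 50)[f$test]), 10)
    expect_equal(sum(rep(0:1, 50)[f$validation]), 8)
  }
  expect_identical(sort(unlist(lapply(sp$folds, `[[`, "test"))), 1:100)
  expect_error(make_cv_splits(100, rep(0:1, 50), K = 1), "K must be >= 2")
  expect_error(make_cv_splits(4, c(0, 0, 0, 1), K = 4), "stratification")
})

test_that("epochs = 0 returns the initialisation with empty history", {
  ts <- separable_trials(n = 20, T = 5, R = 2, seed = 3)
  fit <- tvrnn(ts, strategy = "S1", n_hidden = 4, epochs = 0, seed = 9)
  expect_identical(nrow(fit$history), 0L)
  set.seed(9)
  expect_equal(fit$weights$windows[[1]]$W_h,
               rnn_params(4, 2)$W_h, tolerance = 1e-12)
})

test_that("the RNN solves a separable toy task with held-out accuracy >= 0.95", {
  ts <- separable_trials(n = 200, T = 20, R = 3, seed = 1)
  test_idx <- 161:200
  fit <- tvrnn(ts[1:160], strategy = "S1", n_hidden = 8, epochs = 150,
               learning_rate = 5e-3, seed = 1)
  p <- predict(fit, ts[test_idx])
  acc <- mean(as.integer(p[, 20] >= 0.5) == ts$labels[test_idx])
  expect_gte(acc, 0.95)
  # validation loss at the checkpoint improves on epoch 1
  expect_lte(fit$best_val_loss, fit$history$val_loss[1])
  # fitted/residuals are aligned with the training labels
  expect_length(fitted(fit), length(fit$train_index))
  expect_equal(residuals(fit), fit$train_labels - fitted(fit))
})

test_that("single-window TV training reproduces the S2 run exactly (same seed)", {
  ts <- separable_trials(n = 40, T = 6, R = 2, seed = 4)
  f_s2 <- tvrnn(ts, strategy = "S2", n_hidden = 4, epochs = 15,
                learning_rate = 1e-3, batch_size = 16, seed = 7)
  f_tv <- tvrnn(ts, strategy = "TV", window_size = 6, n_hidden = 4,
                epochs = 15, learning_rate = 1e-3, batch_size = 16, seed = 7)
  expect_identical(f_s2$history$train_loss, f_tv$history$train_loss)
  expect_identical(f_s2$history$val_loss, f_tv$history$val_loss)
  expect_equal(f_s2$weights$windows[[1]], f_tv$weights$windows[[1]],
               tolerance = 1e-12)
})

test_that("training is deterministic given the seed and records gradient traces", {
  ts <- separable_trials(n = 40, T = 8, R = 2, seed = 5)
  a <- tvrnn(ts, strategy = "TV", window_size = 4, n_hidden = 4, epochs = 10,
             seed = 3)
  b <- tvrnn(ts, strategy = "TV", window_size = 4, n_hidden = 4, epochs = 10,
             seed = 3)
  expect_identical(a$history, b$history)
  expect_identical(a$weights$windows, b$weights$windows)
  expect_identical(nrow(a$gradient_trace), 10L * 2L)  # epochs x windows
  expect_true(all(a$gradient_trace$flag %in%
                    c("ok", "vanishing", "exploding")))
  # warm start clones the static fit into every window
  ws <- tvrnn(ts, strategy = "TV", window_size = 4, n_hidden = 4, epochs = 0,
              seed = 3, warm_start = tvrnn(ts, strategy = "S1", n_hidden = 4,
                                           epochs = 5, seed = 3))
  expect_equal(ws$weights$windows[[1]], ws$weights$windows[[2]],
               tolerance = 1e-12)
})

test_that("sliding baselines produce one classifier per window", {
  ts <- separable_trials(n = 80, T = 40, R = 2, gap = 0.6, seed = 6)
  svm_fit <- sliding_baseline(ts[1:60], kind = "svm_rbf", window_len = 10)
  expect_length(svm_fit$fits, 4L)
  expect_identical(svm_fit$window_end, c(10L, 20L, 30L, 40L))
  pr <- predict(svm_fit, ts[61:80])
  expect_identical(dim(pr), c(20L, 4L))
  acc <- colMeans((pr >= 0.5) == matrix(ts$labels[61:80], 20, 4))
  expect_true(all(acc >= 0.95))  # separable task

  # uninformative (near-zero) input: held-out accuracy sits near chance
  set.seed(8)
  z <- trial_set(array(rnorm(60 * 20 * 2, sd = 1e-3), c(60, 20, 2)),
                 rep(c(0L, 1L), 30))
  zfit <- sliding_baseline(z[1:40], kind = "svm_rbf", window_len = 10)
  zacc <- colMeans((predict(zfit, z[41:60]) >= 0.5) ==
                     matrix(z$labels[41:60], 20, 2))
  expect_true(all(abs(zacc - 0.5) <= 0.25))

  # independent RNNs: window j ignores data outside window j
  rfit <- sliding_baseline(ts[1:60], kind = "independent_rnn_s1",
                           window_len = 20, n_hidden = 4, epochs = 5,
                           seed = 1)
  expect_length(rfit$fits, 2L)
  Xp <- ts$data[61:80, , , drop = FALSE]
  Xq <- Xp; Xq[, 21:40, ] <- 0
  expect_identical(predict(rfit, Xp)[, 1], predict(rfit, Xq)[, 1])
})
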