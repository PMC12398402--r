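# linear toy model registered so the integrated-gradient machinery can be
# checked against the closed form IG_i = a_i (x_i - x'_i)
linear_toy <- function(a, b = 0) structure(list(a = a, b = b),
                                           class = "linear_toy")
input_gradient.linear_toy <- function(model, x, output_time) {
  X <- if (is.array(x)) x else array(x, dim = c(1, dim(x)))
  n <- dim(X)[1]
  G <- array(0, dim = dim(X))
  yv <- numeric(n)
  for (i in seq_len(n)) {
    G[i, , ] <- model$a
    yv[i] <- sum(model$a * X[i, , ]) + model$b
  }
  list(grad = G, y = yv)
}
registerS3method("input_gradient", "linear_toy", input_gradient.linear_toy,
                 envir = asNamespace("tvrnn"))

test_that("a zero path yields zero attributions", {
  tv <- rand_tv(2, 3, 6, N = 3, R = 2, seed = 1)
  x <- matrix(rnorm(12), 6, 2)
  att <- integrated_gradients(tv, x, x_prime = x, output_time = 6, steps = 8)
  expect_true(all(att$phi == 0))
  expect_equal(att$f_x, att$f_baseline)
})

test_that("integrated gradients are exact for a linear model", {
  set.seed(2)
  a <- matrix(rnorm(8), 4, 2)
  m <- linear_toy(a, b = 0.3)
  x <- matrix(rnorm(8), 4, 2)
  xp <- matrix(rnorm(8, sd = 0.5), 4, 2)
  att <- integrated_gradients(m, x, x_prime = xp, output_time = 4, steps = 4)
  expect_equal(att$phi, a * (x - xp), tolerance = 1e-12)
  expect_lt(att$completeness_error, 1e-12)
})

test_that("completeness holds within tolerance and tightens with more steps", {
  set.seed(3)
  errs_coarse <- errs_fine <- numeric(3)
  for (r in 1:3) {
    tv <- rand_tv(2, 3, 6, N = 3, R = 2, seed = 30 + r, scale = 0.8)
    x <- matrix(rnorm(12), 6, 2)
    a512 <- integrated_gradients(tv, x, output_time = 6, steps = 512)
    expect_lt(a512$completeness_error, 1e-3)
    expect_equal(sum(a512$phi), a512$f_x - a512$f_baseline, tolerance = 1e-3)
    errs_coarse[r] <- integrated_gradients(tv, x, output_time = 6,
                                           steps = 16)$completeness_error
    errs_fine[r] <- integrated_gradients(tv, x, output_time = 6,
                                         steps = 256)$completeness_error
  }
  expect_true(all(errs_fine <= errs_coarse + 1e-12))
})

test_that("importance is zero for dead channels and for post-output times", {
  # channel 2 disconnected in every window
  tv <- rand_tv(2, 3, 6, N = 3, R = 3, seed = 4)
  for (k in 1:2) tv$windows[[k]]$W_x[, 2] <- 0
  X <- rand_trials(5, 6, 3, seed = 5)
  im <- importance_matrix(tv, X, output_time = 4, steps = 32)
  expect_true(all(im$importance[, 2] == 0))
  # causal model explained at t = 4: inputs after 4 cannot matter
  expect_true(all(abs(im$importance[5:6, ]) <= 1e-6))
  expect_true(all(im$importance >= 0))
  expect_identical(dim(im$phi), c(5L, 6L, 3L))
  # deterministic: identical repeated computation
  im2 <- importance_matrix(tv, X, output_time = 4, steps = 32)
  expect_identical(im$importance, im2$importance)
  expect_error(importance_matrix(tv, X, output_time = 9), "output_time")
})

test_that("attributions concentrate where the model reads input, matching a finite-difference oracle", {
  # only window 2 (time points 4..6) reads the input
  tv <- rand_tv(3, 3, 9, N = 2, R = 2, seed = 6, scale = 0.7)
  for (k in c(1, 3)) tv$windows[[k]]$W_x[] <- 0
  set.seed(7)
  x <- matrix(rnorm(18), 9, 2)
  att <- integrated_gradients(tv, x, output_time = 9, steps = 256)
  expect_true(all(att$phi[c(1:3, 7:9), ] == 0))
  expect_gt(max(abs(att$phi[4:6, ])), 0)
  # finite-difference path-gradient oracle (central differences through the
  # double-precision forward pass, no analytic gradients)
  f_of <- function(xm) {
    tvrnn_forward(tv, array(xm, dim = c(1, 9, 2)))$y[1, 9]
  }
  alpha <- seq(0, 1, length.out = 257)
  w <- c(1, rep(2, 255), 1) / 512
  eps <- 1e-5
  fd_phi <- matrix(0, 9, 2)
  for (idx in which(att$phi != 0)) {
    g <- 0
    for (j in seq_along(alpha)) {
      xa <- alpha[j] * x
      xp <- xa; xp[idx] <- xp[idx] + eps
      xm <- xa; xm[idx] <- xm[idx] - eps
      g <- g + w[j] * (f_of(xp) - f_of(xm)) / (2 * eps)
    }
    fd_phi[idx] <- x[idx] * g
  }
  nz <- att$phi != 0
  expect_equal(att$phi[nz], fd_phi[nz], tolerance = 0.1)
})

test_that("duplicated channels share their attribution symmetrically", {
  set.seed(8)
  base <- rand_tv(1, 5, 5, N = 3, R = 2, seed = 9)
  dup <- base
  # add channel 3 duplicating channel 2, splitting its input weights
  for (k in seq_along(dup$windows)) {
    Wx <- dup$windows[[k]]$W_x
    dup$windows[[k]]$W_x <- cbind(Wx[, 1], Wx[, 2] / 2, Wx[, 2] / 2)
  }
  dup$n_channels <- 3L
  x2 <- matrix(rnorm(10), 5, 2)
  x3 <- cbind(x2[, 1], x2[, 2], x2[, 2])
  att <- integrated_gradients(dup, x3, output_time = 5, steps = 256)
  expect_equal(att$phi[, 2], att$phi[, 3], tolerance = 1e-8)
})

test_that("the zero-baseline output sits at 0.5 for zero-bias models", {
  tv <- rand_tv(2, 2, 4, N = 2, R = 2, seed = 10)
  for (k in 1:2) { tv$windows[[k]]$b_h[] <- 0; tv$windows[[k]]$b_y <- 0 }
  expect_identical(baseline_output(tv), 0.5)
  p <- causal_transformer_params(4, 2, n_layers = 1, n_heads = 2,
                                 d_model = 4, seed = 11)
  p$w_out[] <- 0
  expect_identical(baseline_output(p), 0.5)
  # trained (non-zero-bias) models stay inside (0, 1)
  tv$windows[[1]]$b_y <- 0.3
  b <- baseline_output(tv, output_time = 2)
  expect_true(b > 0 && b < 1)
})

test_that("transformer attributions are causal and converge toward completeness", {
  p <- causal_transformer_params(5, 2, n_layers = 1, n_heads = 2,
                                 d_model = 4, seed = 12)
  set.seed(12)
  x <- matrix(rnorm(10), 5, 2)
  att <- integrated_gradients(p, x, output_time = 3, steps = 512)
  expect_true(all(abs(att$phi[4:5, ]) <= 1e-12))
  # layer normalisation makes the path gradient locally steep near the zero
  # baseline, so the quadrature converges much more slowly than for the
  # RNNs; the error must shrink under refinement and become small once the
  # grid resolves the steep region
  coarse <- integrated_gradients(p, x, output_time = 3, steps = 32)
  fine <- integrated_gradients(p, x, output_time = 3, steps = 4096)
  expect_lt(att$completeness_error, coarse$completeness_error)
  expect_lt(fine$completeness_error, att$completeness_error)
  expect_lt(fine$completeness_error, 0.05)
})
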