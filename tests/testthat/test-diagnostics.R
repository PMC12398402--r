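test_that("Jacobian product norms match closed forms for scaled identities", {
  s <- jacobian_product_norms(2 * diag(3), horizons = 1:5)
  expect_equal(s$log_norms$log_norm[5], log(32), tolerance = 1e-12)
  expect_equal(s$lambda, log(2), tolerance = 1e-12)
  expect_equal(s$spectral_radius, 2, tolerance = 1e-12)
  id <- jacobian_product_norms(diag(4), horizons = c(1, 10, 50))
  expect_equal(id$log_norms$log_norm, rep(0, 3))
  expect_equal(id$lambda, 0, tolerance = 1e-12)
  expect_error(jacobian_product_norms(matrix(1, 2, 3)), "square")
})

test_that("window products equal naive sequential multiplication", {
  set.seed(1)
  Ws <- replicate(6, matrix(rnorm(9, sd = 0.6), 3, 3), simplify = FALSE)
  s <- jacobian_product_norms(Ws, horizons = c(2, 4, 6), window_size = 1)
  P <- diag(3)
  naive <- numeric(0)
  for (j in 1:6) {
    P <- Ws[[j]] %*% P
    if (j %% 2 == 0) naive <- c(naive, log(max(colSums(abs(P)))))
  }
  expect_equal(s$log_norms$log_norm, naive, tolerance = 1e-9)
  # window_size > 1 repeats each factor w times
  s2 <- jacobian_product_norms(Ws[1:2], horizons = 4, window_size = 2)
  P2 <- Ws[[2]] %*% Ws[[2]] %*% Ws[[1]] %*% Ws[[1]]
  expect_equal(s2$log_norms$log_norm, log(max(colSums(abs(P2)))),
               tolerance = 1e-12)
  expect_error(jacobian_product_norms(Ws[1:2], horizons = 10), "window")
})

test_that("fitted Lyapunov exponent recovers the spectral radius for normal matrices", {
  set.seed(2)
  A <- matrix(rnorm(16), 4, 4)
  W <- (A + t(A)) / 2          # symmetric, hence normal
  W <- W / max(Mod(eigen(W)$values)) * 0.9
  s <- jacobian_product_norms(W, horizons = 50:80)
  expect_equal(s$lambda, log(0.9), tolerance = 1e-3)
})

test_that("the induced 1-norm is submultiplicative on random draws", {
  set.seed(3)
  n1 <- function(M) max(colSums(abs(M)))
  for (r in 1:20) {
    A <- matrix(rnorm(25), 5, 5); B <- matrix(rnorm(25), 5, 5)
    expect_lte(n1(A %*% B), n1(A) * n1(B) + 1e-12)
  }
})

test_that("time-varying products grow more slowly than static powers on a Gaussian ensemble", {
  g <- gradient_inequality_experiment(n_hidden = 16, horizon = 30,
                                      n_draws = 60, seed = 4)
  expect_lt(g$mean_tv, g$mean_static)
  expect_lt(g$p_value, 0.05)
  # degenerate ensemble: both sides identical, no significance
  W <- matrix(rnorm(16, sd = 0.3), 4, 4)
  gd <- gradient_inequality_experiment(n_hidden = 4, horizon = 10,
                                       n_draws = 30, fixed_matrix = W)
  expect_equal(gd$log_norm_tv, gd$log_norm_static)
  expect_equal(gd$p_value, 1)
  # horizon 1: one factor on each side, same law -> means close
  g1 <- gradient_inequality_experiment(n_hidden = 16, horizon = 1,
                                       n_draws = 400, seed = 5)
  se <- sd(g1$log_norm_tv - g1$log_norm_static) / sqrt(400)
  expect_lt(abs(g1$mean_tv - g1$mean_static), 4 * se)
  expect_error(gradient_inequality_experiment(n_draws = 10), "n_draws")
})

test_that("weight distance maps are metrics and localise single-entry changes", {
  tv <- rand_tv(3, 2, 6, N = 3, R = 2, seed = 6)
  # identical windows: all-zero maps
  same <- tv_weights(rep(list(tv$windows[[1]]), 3), 2, 6)
  m0 <- weight_distance_map(same)
  expect_true(all(m0$input == 0) && all(m0$recurrent == 0) &&
                all(m0$output == 0))
  # single-entry perturbation of W_h shows up only in the recurrent map
  pert <- same
  pert$windows[[2]]$W_h[1, 1] <- pert$windows[[2]]$W_h[1, 1] + 0.25
  mp <- weight_distance_map(pert)
  expect_equal(mp$recurrent[1, 2], 0.25, tolerance = 1e-12)
  expect_equal(mp$recurrent[2, 3], 0.25, tolerance = 1e-12)
  expect_equal(mp$recurrent[1, 3], 0, tolerance = 1e-12)
  expect_true(all(mp$input == 0) && all(mp$output == 0))
  # random windows: elementwise-difference Frobenius oracle + metric axioms
  m <- weight_distance_map(tv)
  for (a in 1:3) for (b in 1:3) {
    expect_equal(m$recurrent[a, b],
                 sqrt(sum((tv$windows[[a]]$W_h - tv$windows[[b]]$W_h)^2)),
                 tolerance = 1e-12)
    for (cc in 1:3)
      expect_lte(m$input[a, b], m$input[a, cc] + m$input[cc, b] + 1e-12)
  }
  expect_equal(m$output, t(m$output))
  expect_true(all(diag(m$recurrent) == 0))
  expect_error(weight_distance_map(tv_weights(tv$windows[1], 6, 6)),
               ">= 2 windows")
})

test_that("output trajectories summarise class separation", {
  # untrained zero model: both classes at 0.5, no divergence
  Y <- matrix(0.5, 10, 6)
  labs <- rep(c(0L, 1L), 5)
  ot <- output_trajectories(Y, labels = labs)
  expect_equal(ot$mean["control", ], rep(0.5, 6))
  expect_equal(ot$mean["behavior", ], rep(0.5, 6))
  expect_true(is.na(ot$divergence_index))
  # perfect separation from t = 1
  Yp <- matrix(rep(ifelse(labs == 1L, 0.95, 0.05), 6), 10, 6)
  expect_identical(output_trajectories(Yp, labels = labs)$divergence_index, 1L)
  expect_error(output_trajectories(Y, labels = rep(1L, 10)), "class")
})
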