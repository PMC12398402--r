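test_that("temporal accuracy equals direct confusion-count arithmetic", {
  # two folds engineered to give (TP,TN,FP,FN) = (3,3,2,2) and (4,4,1,1)
  lab1 <- c(rep(1L, 5), rep(0L, 5))
  p1 <- matrix(c(rep(0.9, 3), rep(0.1, 2), rep(0.1, 3), rep(0.9, 2)), 10, 1)
  lab2 <- c(rep(1L, 5), rep(0L, 5))
  p2 <- matrix(c(rep(0.9, 4), 0.1, rep(0.1, 4), 0.9), 10, 1)
  cu <- temporal_accuracy(list(p1, p2), list(lab1, lab2))
  expect_identical(cu$confusion[1, 1, ], c(TP = 3L, TN = 3L, FP = 2L, FN = 2L))
  expect_identical(cu$confusion[2, 1, ], c(TP = 4L, TN = 4L, FP = 1L, FN = 1L))
  expect_equal(cu$accuracy, (0.6 + 0.8) / 2)
  expect_equal(cu$chance_level, 0.5)

  # perfect predictions
  perf <- temporal_accuracy(list(matrix(lab1, 10, 4), matrix(lab2, 10, 4)),
                            list(lab1, lab2))
  expect_equal(perf$accuracy, rep(1, 4))

  # constant 0.5 with the tie rule: everything called class 1
  tie <- temporal_accuracy(list(matrix(0.5, 10, 2), matrix(0.5, 10, 2)),
                           list(lab1, c(rep(1L, 3), rep(0L, 7))))
  expect_equal(tie$per_fold[1, ], rep(0.5, 2))
  expect_equal(tie$per_fold[2, ], rep(0.3, 2))

  expect_error(temporal_accuracy(list(p1), list(lab1)), "folds")
  expect_error(
    temporal_accuracy(list(p1, p2[0, , drop = FALSE]),
                      list(lab1, integer(0))), "empty fold")
})

test_that("temporal accuracy matches a direct counting oracle on random tables", {
  set.seed(21)
  for (rep in 1:20) {
    K <- sample(2:5, 1); n <- sample(5:30, 1); Tn <- sample(1:6, 1)
    preds <- lapply(seq_len(K), function(k) matrix(runif(n * Tn), n, Tn))
    labs <- lapply(seq_len(K), function(k) sample(0:1, n, replace = TRUE))
    if (any(vapply(labs, function(l) length(unique(l)), 1L) < 1L)) next
    cu <- temporal_accuracy(preds, labs)
    oracle <- sapply(seq_len(Tn), function(t)
      mean(vapply(seq_len(K), function(k)
        mean(as.integer(preds[[k]][, t] >= 0.5) == labs[[k]]), numeric(1))))
    expect_equal(cu$accuracy, oracle, tolerance = 1e-12)
    expect_true(all(cu$per_fold >= 0 & cu$per_fold <= 1))
  }
})

test_that("AUAC integrates the curve above chance", {
  # accuracy identically at chance -> 0
  flat <- curve_from_folds(matrix(0.5, 2, 11), time_seconds = seq(0, 10))
  expect_equal(auac(flat), 0)
  # accuracy 1.0, chance 0.5, 10 s span -> 5 accuracy-seconds
  rect <- curve_from_folds(matrix(1, 2, 11), time_seconds = seq(0, 10))
  expect_equal(auac(rect), 5)
  expect_equal(auac(rect, 2, 6), 2)
  # negative excursions are not clipped
  below <- curve_from_folds(matrix(0.25, 2, 3), time_seconds = 0:2)
  expect_equal(auac(below), -0.5)
  expect_error(auac(rect, 6, 2), "t_start")
})

test_that("AUAC matches a midpoint-refined Riemann oracle and is linear in shifts", {
  set.seed(31)
  tt <- sort(runif(40, 0, 12))
  acc <- runif(40, 0.3, 1)
  cu <- curve_from_folds(rbind(acc, acc), time_seconds = tt)
  # piecewise-linear interpolant integrated by midpoint rule per segment
  # (exact for linear pieces)
  riemann <- sum(vapply(seq_len(39), function(i) {
    m <- 200
    xs <- seq(tt[i], tt[i + 1], length.out = m + 1)
    mid <- (xs[-1] + xs[-(m + 1)]) / 2
    f <- approx(tt, acc - 0.5, xout = mid)$y
    sum(f * diff(xs))
  }, numeric(1)))
  expect_equal(auac(cu), riemann, tolerance = 1e-9)
  shifted <- curve_from_folds(rbind(acc + 0.1, acc + 0.1), time_seconds = tt)
  expect_equal(auac(shifted), auac(cu) + 0.1 * (tt[40] - tt[1]),
               tolerance = 1e-9)
})

test_that("Benjamini-Hochberg matches the textbook step-up rule", {
  expect_identical(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), 0.05),
                   rep(TRUE, 4))
  expect_identical(benjamini_hochberg(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(benjamini_hochberg(0.04, 0.05), TRUE)
  set.seed(41)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(benjamini_hochberg(p, alpha), bh_stepup_oracle(p, alpha))
  }
  # monotonicity in alpha
  p <- runif(30)^2
  r1 <- benjamini_hochberg(p, 0.05)
  r2 <- benjamini_hochberg(p, 0.1)
  expect_true(all(r2[r1]))
})

test_that("earliest decoding time follows the consistent-suffix rule", {
  # per-fold accuracy identically at chance: no EDT, no onset
  flat <- curve_from_folds(matrix(0.5, 5, 10))
  ed <- earliest_decoding_time(flat)
  expect_true(is.na(ed$edt_index) && is.na(ed$onset_index))
  # strongly significant everywhere: EDT at the first time point
  hi <- curve_from_folds(matrix(rep(c(0.9, 0.92, 0.88, 0.91, 0.9), 10), 5, 10))
  expect_identical(earliest_decoding_time(hi)$edt_index, 1L)
  # significant only on the final 40%: EDT at the start of that suffix
  pf <- matrix(0.5, 5, 10)
  pf[, 7:10] <- rep(c(0.9, 0.92, 0.88, 0.91, 0.9), 4)
  ed <- earliest_decoding_time(curve_from_folds(pf))
  expect_identical(ed$edt_index, 7L)
  expect_identical(ed$onset_index, 7L)
  expect_identical(ed$edt_index,
                   edt_scan_oracle(ed$significant, 10L))
  # zero-variance convention
  const_hi <- curve_from_folds(matrix(0.8, 3, 4))
  expect_equal(earliest_decoding_time(const_hi)$p_values, rep(0, 4))
  const_lo <- curve_from_folds(matrix(0.4, 3, 4))
  expect_equal(earliest_decoding_time(const_lo)$p_values, rep(1, 4))
  # gap tolerance
  gap <- matrix(rep(c(0.9, 0.92, 0.88), 10), 3, 10)
  gap[, 5] <- 0.5
  expect_identical(earliest_decoding_time(curve_from_folds(gap))$edt_index, 6L)
  expect_identical(
    earliest_decoding_time(curve_from_folds(gap), gap_tolerance = 1)$edt_index,
    1L)
})

test_that("EDT matches the exhaustive scan on randomized curves and is monotone", {
  set.seed(51)
  for (rep in 1:60) {
    K <- sample(3:6, 1); Tn <- sample(4:25, 1)
    pf <- matrix(runif(K * Tn, 0.3, 1), K, Tn)
    tz <- sample(seq_len(Tn), 1)
    cu <- curve_from_folds(pf, t_zero = tz)
    ed <- earliest_decoding_time(cu)
    expect_identical(ed$edt_index, edt_scan_oracle(ed$significant, tz))
    # uniformly increasing accuracies never delays the EDT
    up <- curve_from_folds(pmin(pf + 0.05, 1), t_zero = tz)
    ed_up <- earliest_decoding_time(up)
    if (!is.na(ed$edt_index))
      expect_true(!is.na(ed_up$edt_index) &&
                    ed_up$edt_index <= ed$edt_index)
  }
})
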