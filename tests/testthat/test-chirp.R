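test_that("generator produces a balanced, deterministic trial set of the right shape", {
  sp <- chirp_spec(n_trials = 60, n_timepoints = 80, seed = 7)
  ts <- generate_chirp_trials(sp)
  expect_s3_class(ts, "trial_set")
  expect_identical(dim(ts$data), c(60L, 80L, 10L))
  expect_identical(sum(ts$labels == 1L), 30L)
  expect_identical(sum(ts$labels == 0L), 30L)
  expect_identical(ts$t_zero_index, 80L)
  ts2 <- generate_chirp_trials(sp)
  expect_identical(ts$data, ts2$data)
  expect_identical(ts$labels, ts2$labels)
  # different seed differs
  ts3 <- generate_chirp_trials(chirp_spec(n_trials = 60, n_timepoints = 80,
                                          seed = 8))
  expect_false(identical(ts$data, ts3$data))
})

test_that("invalid chirp specs are rejected with the offending field named", {
  expect_error(chirp_spec(coeff_range = c(2, 2)), "coeff_range")
  expect_error(chirp_spec(coeff_range = c(0, 4)), "coeff_range")
  expect_error(chirp_spec(n_trials = 11), "n_trials")
  expect_error(chirp_spec(n_timepoints = 1), "n_timepoints")
  expect_error(chirp_spec(noise_sd = -1), "noise_sd")
})

test_that("controls are jointly time-shuffled behavior trials and the stored permutation round-trips", {
  # keep the sweep slow relative to sampling so behavior trials are smooth
  # (high lag-1 autocorrelation) and shuffling visibly destroys it
  ts <- generate_chirp_trials(chirp_spec(n_trials = 40, n_timepoints = 120,
                                         freq_end = 6, noise_sd = 0.2,
                                         seed = 3))
  perms <- ts$meta$control_perms
  ctrl <- ts$meta$control_index
  expect_identical(ts$labels[ctrl], rep(0L, length(ctrl)))
  lag1 <- function(v) suppressWarnings(cor(v[-1], v[-length(v)]))
  for (j in c(1L, 5L, 20L)) {
    i <- ctrl[j]
    un <- ts$data[i, order(perms[j, ]), ]   # un-shuffle via the stored perm
    # multiset identity per channel: shuffling permutes values, joint across channels
    for (r in 1:10)
      expect_equal(sort(ts$data[i, , r]), sort(un[, r]))
    # the un-shuffled trial is smooth like a behavior trial; the control is not
    expect_gt(lag1(un[, 10]), 0.5)
    expect_lt(abs(lag1(ts$data[i, , 10])), 0.35)
  }
  # joint (not per-channel) shuffling preserves instantaneous cross-channel
  # structure: channels stay strongly correlated in control trials
  i <- ctrl[2L]
  expect_gt(cor(ts$data[i, , 9], ts$data[i, , 10]), 0.5)
})

test_that("behavior-trial variance increases across trial thirds (amplitude ramp)", {
  ts <- generate_chirp_trials(chirp_spec(n_trials = 10, n_timepoints = 300,
                                         noise_sd = 0, seed = 2))
  beh <- ts$data[ts$labels == 1L, , , drop = FALSE]
  v <- vapply(split(seq_len(300), rep(1:3, each = 100)),
              function(idx) var(as.numeric(beh[, idx, ])), numeric(1))
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("noise placement and coefficient options are honoured", {
  base <- generate_chirp_trials(chirp_spec(n_trials = 8, n_timepoints = 50,
                                           noise_sd = 0, seed = 1))
  pre <- generate_chirp_trials(chirp_spec(n_trials = 8, n_timepoints = 50,
                                          noise_sd = 0, seed = 1,
                                          noise_placement = "pre_scaling"))
  expect_equal(base$data, pre$data)  # identical when noiseless
  cf <- generate_chirp_trials(chirp_spec(n_trials = 4, n_timepoints = 20,
                                         seed = 5))$meta$coefficients
  expect_length(cf, 10L)
  expect_true(all(cf > 1 & cf < 4))
  expect_false(anyDuplicated(cf) > 0)
  rc <- generate_chirp_trials(chirp_spec(n_trials = 4, n_timepoints = 20,
                                         seed = 5, random_coeffs = TRUE))
  expect_false(identical(cf, rc$meta$coefficients))
})

test_that("stft magnitude localises a pure tone and tracks the chirp sweep", {
  # pure sinusoid at a bin centre: magnitude maximal in that bin, every frame
  Tn <- 256; fs <- 32; f0 <- 8
  x <- sin(2 * pi * f0 * (0:(Tn - 1)) / fs)
  arr <- array(0, dim = c(2, Tn, 1))
  arr[1, , 1] <- x; arr[2, , 1] <- x
  ts <- trial_set(arr, c(0L, 1L), sampling_rate = fs)
  m <- stft_magnitude(ts, channel = 1, window_len = 64, hop = 16)
  peak_bin <- apply(m$magnitude, 2, which.max)
  expect_true(all(m$freq[peak_bin] == f0))

  # noise-free chirp: dominant bin is non-decreasing across frames
  cs <- generate_chirp_trials(chirp_spec(n_trials = 4, n_timepoints = 300,
                                         noise_sd = 0, seed = 1))
  mc <- stft_magnitude(cs, channel = 3, window_len = 64, hop = 16)
  ridge <- apply(mc$magnitude, 2, which.max)
  expect_true(all(diff(ridge) >= 0))

  # all-zero input has an all-zero magnitude
  z <- trial_set(array(0, dim = c(2, 64, 1)), c(0L, 1L), sampling_rate = 32)
  expect_true(all(stft_magnitude(z, 1, window_len = 32,
                                 class = 0)$magnitude == 0))

  expect_error(stft_magnitude(ts, channel = 5), "out of range")
  expect_error(stft_magnitude(ts, channel = 1, window_len = 1000),
               "window_len")
})
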