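# Shared fixture builders.  Everything is generated in code at test time.

# small random trial array
rand_trials <- function(n = 4, T = 6, R = 3, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(n * T * R, sd = sd), dim = c(n, T, R))
}

# random tv_weights bundle with small entries
rand_tv <- function(n_win, w, T, N = 3, R = 3, seed = NULL, scale = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  tv_weights(lapply(seq_len(n_win), function(k) {
    p <- rnn_params(N, R, scale = scale)
    p$b_h <- runif(N, -0.1, 0.1)
    p$b_y <- runif(1, -0.1, 0.1)
    p
  }), window_size = w, n_timepoints = T)
}

# linearly separable toy task: class = sign of the channel mean
separable_trials <- function(n = 200, T = 20, R = 3, gap = 0.5, noise = 0.2,
                             seed = 1) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  X <- array(rnorm(n * T * R, sd = noise), dim = c(n, T, R))
  X <- X + array(rep(ifelse(labels == 1L, gap, -gap), T * R),
                 dim = c(n, T, R))
  trial_set(X, labels, sampling_rate = 10)
}

# build a temporal_accuracy_curve directly from a per-fold accuracy matrix
curve_from_folds <- function(per_fold, chance = 0.5, time_seconds = NULL,
                             t_zero = ncol(per_fold)) {
  structure(list(accuracy = colMeans(per_fold), per_fold = per_fold,
                 confusion = NULL, chance_level = chance,
                 time_seconds = time_seconds %||% as.numeric(seq_len(ncol(per_fold))),
                 t_zero_index = as.integer(t_zero)),
            class = "temporal_accuracy_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# exhaustive-scan earliest decoding time given significance calls
edt_scan_oracle <- function(sig, t_zero, gap = 0L) {
  for (t0 in seq_len(t_zero))
    if (sum(!sig[t0:t_zero]) <= gap) return(t0)
  NA_integer_
}
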