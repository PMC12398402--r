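# Model containers and forward computation.  A standard RNN is the
# single-window special case of the time-varying machinery: hidden state
# h_t = tanh(W_h h_{t-1} + W_x x_t + b_h) with h_0 = 0, per-time-point output
# y_t = sigmoid(w_y . h_t + b_y), and, for the time-varying model, a separate
# weight bundle per temporal window k = ceiling(t / w) while the hidden state
# flows continuously across window boundaries.

#' One bundle of RNN parameters
#'
#' @param n_hidden Hidden units `N` (default 64).
#' @param n_channels Input channels `R`.
#' @param seed Optional RNG seed for the initial draw.
#' @param scale `"glorot"` (fan-based uniform, the default) or a numeric
#'   scalar: uniform on `[-scale, scale]` for all weight matrices.
#' @return Object of class `rnn_params`: list with `W_x` (`N x R`), `W_h`
#'   (`N x N`), `w_y` (`N`), `b_h` (`N`), `b_y` (scalar).  Biases start at 0.
#' @export
rnn_params <- function(n_hidden = 64, n_channels, seed = NULL,
                       scale = "glorot") {
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_hidden); R <- as.integer(n_channels)
  lim <- function(fan_in, fan_out)
    if (identical(scale, "glorot")) sqrt(6 / (fan_in + fan_out)) else scale
  p <- list(
    W_x = matrix(runif(N * R, -1, 1) * lim(R, N), N, R),
    W_h = matrix(runif(N * N, -1, 1) * lim(N, N), N, N),
    w_y = runif(N, -1, 1) * lim(N, 1),
    b_h = rep(0, N),
    b_y = 0)
  class(p) <- "rnn_params"
  validate_rnn_params(p)
  p
}

validate_rnn_params <- function(p) {
  N <- nrow(p$W_h)
  if (ncol(p$W_h) != N) stop("W_h must be square", call. = FALSE)
  if (nrow(p$W_x) != N) stop("W_x must have N rows", call. = FALSE)
  if (length(p$w_y) != N || length(p$b_h) != N || length(p$b_y) != 1L)
    stop("rnn_params shapes are inconsistent", call. = FALSE)
  if (!all(vapply(p[c("W_x", "W_h", "w_y", "b_h", "b_y")],
                  function(m) all(is.finite(m)), logical(1))))
    stop("rnn_params contain non-finite values", call. = FALSE)
  invisible(p)
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("<rnn_params> N = %d hidden units, R = %d channels\n",
              nrow(x$W_h), ncol(x$W_x)))
  invisible(x)
}

#' Per-window parameter bundle of a time-varying RNN
#'
#' @param windows List of [rnn_params()] bundles, one per window, all sharing
#'   the hidden and channel dimensions.
#' @param window_size Window length `w` in time points.
#' @param n_timepoints Sequence length `T`; there must be exactly
#'   `ceiling(T / w)` windows (the last window is truncated when `w` does not
#'   divide `T`).
#' @return Object of class `tv_weights`.
#' @export
tv_weights <- function(windows, window_size, n_timepoints) {
  w <- as.integer(window_size); T <- as.integer(n_timepoints)
  if (w < 1L) stop("window_size must be >= 1", call. = FALSE)
  if (length(windows) != ceiling(T / w))
    stop("need ceiling(T / w) = ", ceiling(T / w), " windows, got ",
         length(windows), call. = FALSE)
  lapply(windows, validate_rnn_params)
  N <- nrow(windows[[1]]$W_h); R <- ncol(windows[[1]]$W_x)
  for (win in windows)
    if (nrow(win$W_h) != N || ncol(win$W_x) != R)
      stop("all windows must share N and R", call. = FALSE)
  structure(list(windows = windows, window_size = w, n_timepoints = T,
                 n_hidden = N, n_channels = R),
            class = "tv_weights")
}

#' @export
print.tv_weights <- function(x, ...) {
  cat(sprintf("<tv_weights> %d windows of size %d over T = %d; N = %d, R = %d\n",
              length(x$windows), x$window_size, x$n_timepoints,
              x$n_hidden, x$n_channels))
  invisible(x)
}

#' Window index of a time point
#'
#' Maps a 1-based time index to its window `k = ceiling(t / w)`.  The final
#' window covers fewer than `w` points when `w` does not divide `T`.
#'
#' @param t Time index (vectorised), `1 <= t <= n_timepoints`.
#' @param window_size Window length `w >= 1`.
#' @param n_timepoints Optional sequence length used to range-check `t`.
#' @return Integer window indices (1-based).
#' @examples
#' window_index(30, 30)   # 1
#' window_index(31, 30)   # 2
#' @export
window_index <- function(t, window_size, n_timepoints = NULL) {
  if (window_size < 1L) stop("window_size must be >= 1", call. = FALSE)
  if (any(t < 1L) || (!is.null(n_timepoints) && any(t > n_timepoints)))
    stop("time index out of range", call. = FALSE)
  as.integer(ceiling(t / window_size))
}

# 0-based window assignment per time step, for the compiled core
window_assignment <- function(n_timepoints, window_size)
  window_index(seq_len(n_timepoints), window_size) - 1L

as_input_array <- function(x) {
  if (inherits(x, "trial_set")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop("input must be a trial_set or a [trials x time x channels] array",
       call. = FALSE)
}

as_window_list <- function(params) {
  if (inherits(params, "rnn_params")) list(unclass(params))
  else lapply(params$windows, unclass)
}

make_output_trajectory <- function(fw, n_timepoints) {
  y <- fw$y
  structure(list(y = y,
                 h = fw$h %||% NULL,
                 class_calls = matrix(as.integer(y >= 0.5), nrow(y), ncol(y))),
            class = "output_trajectory")
}

#' Forward pass of a standard RNN
#'
#' Runs the recursion `h_t = tanh(W_h h_{t-1} + W_x x_t + b_h)` from
#' `h_0 = 0` and returns the per-time-point sigmoid outputs.
#'
#' @param params An [rnn_params()] bundle.
#' @param x A [trial_set()] or `[trials x time x channels]` array whose
#'   channel dimension matches `params`.
#' @param keep_hidden If `TRUE`, also return the hidden trajectory
#'   (`[trials x N x time]`).
#' @return Object of class `output_trajectory`: list with `y`
#'   (`trials x time`, strictly inside (0,1)), optional `h`, and
#'   `class_calls` (thresholded at 0.5, ties going to class 1).
#' @export
rnn_forward <- function(params, x, keep_hidden = FALSE) {
  stopifnot(inherits(params, "rnn_params"))
  X <- as_input_array(x)
  if (dim(X)[3L] != ncol(params$W_x))
    stop("channel dimension of input (", dim(X)[3L],
         ") does not match params (", ncol(params$W_x), ")", call. = FALSE)
  fw <- .cpp_forward(X, as_window_list(params),
                     rep(0L, dim(X)[2L]), keep_hidden)
  make_output_trajectory(fw, dim(X)[2L])
}

#' Forward pass of a time-varying RNN
#'
#' Identical recursion to [rnn_forward()] except that at each time step the
#' weight bundle of window `ceiling(t / w)` is used; the hidden state is
#' carried across window boundaries, never reset.
#'
#' @param tv A [tv_weights()] bundle.
#' @param x A [trial_set()] or array; the time dimension must equal
#'   `tv$n_timepoints`.
#' @inheritParams rnn_forward
#' @return An `output_trajectory`, as for [rnn_forward()].
#' @export
tvrnn_forward <- function(tv, x, keep_hidden = FALSE) {
  stopifnot(inherits(tv, "tv_weights"))
  X <- as_input_array(x)
  if (dim(X)[2L] != tv$n_timepoints)
    stop("trial length (", dim(X)[2L], ") does not match tv weights (T = ",
         tv$n_timepoints, ")", call. = FALSE)
  if (dim(X)[3L] != tv$n_channels)
    stop("channel dimension of input (", dim(X)[3L],
         ") does not match tv weights (", tv$n_channels, ")", call. = FALSE)
  fw <- .cpp_forward(X, as_window_list(tv),
                     window_assignment(tv$n_timepoints, tv$window_size),
                     keep_hidden)
  make_output_trajectory(fw, dim(X)[2L])
}

#' @export
print.output_trajectory <- function(x, ...) {
  cat(sprintf("<output_trajectory> %d trials x %d time points%s\n",
              nrow(x$y), ncol(x$y),
              if (!is.null(x$h)) " (hidden states kept)" else ""))
  invisible(x)
}

#' Threshold per-time-point outputs into class calls
#'
#' Class 0 if `y_t < 0.5`, class 1 otherwise (so a tie at exactly 0.5 is
#' called class 1).
#'
#' @param y An `output_trajectory` or a `[trials x time]` probability matrix.
#' @param t Time index at which to classify.
#' @return Integer vector of 0/1 calls, one per trial.
#' @export
classify <- function(y, t) {
  m <- if (inherits(y, "output_trajectory")) y$y else y
  t <- as.integer(t)
  if (t < 1L || t > ncol(m)) stop("time index out of range", call. = FALSE)
  as.integer(m[, t] >= 0.5)
}

# Pure-R scalar-loop reference recursion, used by tests as the independent
# oracle for the compiled forward pass.
rnn_forward_reference <- function(windows, window_size, X) {
  n <- dim(X)[1L]; T <- dim(X)[2L]; R <- dim(X)[3L]
  N <- nrow(windows[[1]]$W_h)
  Y <- matrix(0, n, T)
  for (i in seq_len(n)) {
    h <- rep(0, N)
    for (t in seq_len(T)) {
      w <- windows[[window_index(t, window_size)]]
      a <- rep(0, N)
      for (jj in seq_len(N)) {
        s <- w$b_h[jj]
        for (mm in seq_len(N)) s <- s + w$W_h[jj, mm] * h[mm]
        for (rr in seq_len(R)) s <- s + w$W_x[jj, rr] * X[i, t, rr]
        a[jj] <- tanh(s)
      }
      h <- a
      z <- w$b_y
      for (jj in seq_len(N)) z <- z + w$w_y[jj] * h[jj]
      Y[i, t] <- 1 / (1 + exp(-z))
    }
  }
  Y
}
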