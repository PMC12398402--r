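# SHAP-style importance via integrated gradients.  The model output being
# explained is F(x) = y at a chosen output time; attributions are the
# straight-line path integral of the input gradient from a baseline trial
# (all zeros by default, whose sigmoid output sits near 0.5), approximated
# with the trapezoid rule.  Summing attributions over all inputs recovers
# F(x) - F(baseline) (completeness), which is checked and reported.

#' Gradient of a model output with respect to its inputs
#'
#' @param model A fitted [tvrnn()], a [tv_weights()]/[rnn_params()] bundle,
#'   a fitted [causal_transformer()], or [causal_transformer_params()].
#' @param x A `[trials x time x channels]` array or [trial_set()].
#' @param output_time Time index of the output `y_t` being differentiated.
#' @return List with `grad` (`[trials x time x channels]`, zero at input
#'   times after `output_time` for these causal models) and `y` (the model
#'   outputs at `output_time`).
#' @export
input_gradient <- function(model, x, output_time) UseMethod("input_gradient")

#' @export
input_gradient.tvrnn <- function(model, x, output_time)
  input_gradient(model$weights, x, output_time)

#' @export
input_gradient.tv_weights <- function(model, x, output_time) {
  X <- as_input_array(x)
  Tn <- dim(X)[2L]
  if (output_time < 1L || output_time > Tn)
    stop("output_time outside the trial (1..", Tn, ")", call. = FALSE)
  res <- .cpp_input_grad(X, lapply(model$windows, unclass),
                         window_assignment(model$n_timepoints,
                                           model$window_size),
                         as.integer(output_time) - 1L)
  if (!all(is.finite(res$grad)))
    stop("non-finite input gradients", call. = FALSE)
  list(grad = res$grad, y = res$y)
}

#' @export
input_gradient.rnn_params <- function(model, x, output_time) {
  X <- as_input_array(x)
  input_gradient(tv_weights(list(model), window_size = dim(X)[2L],
                            n_timepoints = dim(X)[2L]),
                 X, output_time)
}

#' @export
input_gradient.causal_transformer <- function(model, x, output_time)
  input_gradient(model$weights, x, output_time)

#' @export
input_gradient.transformer_params <- function(model, x, output_time) {
  X <- as_input_array(x)
  n <- dim(X)[1L]; Tn <- dim(X)[2L]; R <- dim(X)[3L]
  if (output_time < 1L || output_time > Tn)
    stop("output_time outside the trial (1..", Tn, ")", call. = FALSE)
  G <- array(0, dim = c(n, Tn, R))
  yv <- numeric(n)
  for (i in seq_len(n)) {
    fw <- tf_forward_trial(model, matrix(X[i, , ], Tn, R), cache = TRUE)
    dz <- numeric(Tn)
    dz[output_time] <- fw$y[output_time] * (1 - fw$y[output_time])
    bw <- tf_backward_trial(model, fw$cache, dz)
    G[i, , ] <- bw$dX
    yv[i] <- fw$y[output_time]
  }
  if (!all(is.finite(G))) stop("non-finite input gradients", call. = FALSE)
  list(grad = G, y = yv)
}

#' Integrated-gradient attribution of one trial
#'
#' Approximates the path integral
#' `(x_i - x'_i) * integral over alpha of dF(x' + alpha (x - x')) / dx_i`
#' with the trapezoid rule over `steps` intervals on the straight line from
#' the baseline `x_prime` to `x`; `F` is the model output at `output_time`.
#' The completeness identity (attributions summing to `F(x) - F(x')`) holds
#' up to the quadrature error, which shrinks as `steps` grows.
#'
#' @param model See [input_gradient()].
#' @param x A single trial (`[time x channels]` matrix).
#' @param x_prime Baseline trial of the same shape (default: all zeros).
#' @param output_time Output time index being explained.
#' @param steps Trapezoid-rule intervals (default 128).
#' @return Object of class `ig_attribution`: `phi` (`time x channels`
#'   signed attributions), `f_x`, `f_baseline`, `completeness_error`
#'   (`|sum(phi) - (f_x - f_baseline)|`).
#' @export
integrated_gradients <- function(model, x, x_prime = NULL, output_time,
                                 steps = 128) {
  x <- as.matrix(x)
  Tn <- nrow(x); R <- ncol(x)
  if (is.null(x_prime)) x_prime <- matrix(0, Tn, R)
  stopifnot(identical(dim(x_prime), dim(x)), steps >= 1)
  alpha <- seq(0, 1, length.out = steps + 1L)
  wts <- c(1, rep(2, steps - 1L), 1) / (2 * steps)
  # evaluate all path points as one batch
  Xa <- array(0, dim = c(steps + 1L, Tn, R))
  for (j in seq_along(alpha))
    Xa[j, , ] <- x_prime + alpha[j] * (x - x_prime)
  ig <- input_gradient(model, Xa, output_time)
  if (!all(is.finite(ig$grad))) {
    bad <- which(!apply(is.finite(ig$grad), 1, all))[1]
    stop("non-finite gradient on the integration path at alpha = ",
         signif(alpha[bad], 4), call. = FALSE)
  }
  avg <- matrix(0, Tn, R)
  for (j in seq_along(alpha)) avg <- avg + wts[j] * ig$grad[j, , ]
  phi <- (x - x_prime) * avg
  f_b <- ig$y[1L]; f_x <- ig$y[steps + 1L]
  structure(list(phi = phi, f_x = f_x, f_baseline = f_b,
                 completeness_error = abs(sum(phi) - (f_x - f_b)),
                 output_time = output_time, steps = steps),
            class = "ig_attribution")
}

#' @export
print.ig_attribution <- function(x, ...) {
  cat(sprintf("<ig_attribution> output time %d, %d steps: F(x) = %.4f, F(baseline) = %.4f, completeness error %.2e\n",
              x$output_time, x$steps, x$f_x, x$f_baseline,
              x$completeness_error))
  invisible(x)
}

#' Time-by-channel importance matrix over test trials
#'
#' Runs [integrated_gradients()] for every trial (zero or class-mean
#' baseline) and averages the absolute attributions across trials, the
#' importance map of the input features conditioned on one output time.
#' The signed mean is also kept.
#'
#' @param model See [input_gradient()].
#' @param x Test trials ([trial_set()] or array).
#' @param output_time Output time index being explained.
#' @param steps Trapezoid-rule intervals (default 128).
#' @param baseline `"zero"` (default) or `"class_mean"` (mean control
#'   trial; requires a trial set).
#' @return Object of class `attribution_matrix`: `phi`
#'   (`[trials x time x channels]` signed), `importance` (`time x channels`,
#'   mean absolute), `signed_mean`, `output_time`, `baseline`,
#'   `f_baseline`, `max_completeness_error`.
#' @export
importance_matrix <- function(model, x, output_time, steps = 128,
                              baseline = c("zero", "class_mean")) {
  baseline <- match.arg(baseline)
  X <- as_input_array(x)
  n <- dim(X)[1L]; Tn <- dim(X)[2L]; R <- dim(X)[3L]
  if (output_time < 1L || output_time > Tn)
    stop("output_time outside the trial (1..", Tn, ")", call. = FALSE)
  x_prime <- if (baseline == "zero") matrix(0, Tn, R) else {
    if (!inherits(x, "trial_set"))
      stop("class_mean baseline requires a trial_set", call. = FALSE)
    apply(X[x$labels == 0L, , , drop = FALSE], c(2, 3), mean)
  }
  phi <- array(0, dim = c(n, Tn, R))
  errs <- numeric(n); fb <- NA_real_
  for (i in seq_len(n)) {
    att <- integrated_gradients(model, matrix(X[i, , ], Tn, R),
                                x_prime = x_prime,
                                output_time = output_time, steps = steps)
    phi[i, , ] <- att$phi
    errs[i] <- att$completeness_error
    fb <- att$f_baseline
  }
  structure(list(
    phi = phi,
    importance = apply(abs(phi), c(2, 3), mean),
    signed_mean = apply(phi, c(2, 3), mean),
    output_time = as.integer(output_time), steps = steps,
    baseline = baseline, f_baseline = fb,
    max_completeness_error = max(errs)),
    class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("<attribution_matrix> %d trials x %d time points x %d channels at output time %d\n",
              dim(x$phi)[1], dim(x$phi)[2], dim(x$phi)[3], x$output_time))
  cat(sprintf("  baseline %s (F = %.4f); max completeness error %.2e\n",
              x$baseline, x$f_baseline, x$max_completeness_error))
  invisible(x)
}

#' @export
plot.attribution_matrix <- function(x, ...) {
  image(seq_len(nrow(x$importance)), seq_len(ncol(x$importance)),
        x$importance, xlab = "time point", ylab = "channel",
        main = sprintf("importance (output time %d)", x$output_time), ...)
  invisible(x)
}

#' Model output on the all-zero baseline trial
#'
#' Reported alongside attributions so the completeness identity can be
#' checked; for sigmoid heads with zero biases this is exactly 0.5, and it
#' stays near 0.5 for trained models.
#'
#' @param model See [input_gradient()].
#' @param n_timepoints Trial length (defaults to the model's).
#' @param output_time Output time (default: last time point).
#' @return Scalar output on the zero trial.
#' @export
baseline_output <- function(model, n_timepoints = NULL, output_time = NULL) {
  dims <- if (inherits(model, "tvrnn"))
    list(T = model$n_timepoints, R = model$n_channels)
  else if (inherits(model, "tv_weights"))
    list(T = model$n_timepoints, R = model$n_channels)
  else if (inherits(model, "rnn_params"))
    list(T = NULL, R = ncol(model$W_x))
  else {
    cf <- attr(if (inherits(model, "causal_transformer")) model$weights
               else model, "config")
    list(T = cf$n_timepoints, R = cf$n_channels)
  }
  Tn <- n_timepoints %||% dims$T
  if (is.null(Tn))
    stop("n_timepoints is required for a bare rnn_params bundle",
         call. = FALSE)
  output_time <- output_time %||% Tn
  ig <- input_gradient(model, array(0, dim = c(1L, Tn, dims$R)), output_time)
  ig$y[1L]
}
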