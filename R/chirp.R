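#' Specification of the simulated chirp dataset
#'
#' Describes a synthetic trial-structured dataset in which each 'behavior'
#' trial carries the same linear-frequency chirp on every channel, scaled by
#' a distinct per-channel coefficient, with a linearly increasing amplitude
#' ramp and additive Gaussian noise; 'control' trials are behavior trials
#' whose time indices have been randomly permuted (jointly across channels),
#' destroying temporal order while preserving the per-trial value
#' distribution.  The sweep makes the signal statistics drift from low
#' frequency / low amplitude early in the trial to high frequency / high
#' amplitude late, the distribution shift the time-varying models are
#' designed to exploit.
#'
#' @param n_channels Number of channels (default 10).
#' @param n_timepoints Time points per trial (default 300).
#' @param n_trials Total trials, split equally between classes (default 2000,
#'   must be even).
#' @param coeff_range Open interval for the distinct per-channel multipliers
#'   (default `c(1, 4)`; lower bound must be positive).
#' @param freq_start,freq_end Chirp frequency sweep endpoints in cycles per
#'   trial (defaults 2 and 30).
#' @param amp_start,amp_end Amplitude ramp endpoints (defaults 0.2 and 1).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (default 0.5).
#' @param sampling_rate Time points per second (default 30, so the default
#'   trial spans 10 s).
#' @param random_coeffs If `TRUE`, draw the channel coefficients uniformly
#'   from `coeff_range` instead of spacing them evenly (default `FALSE`:
#'   even spacing is deterministic given the spec).
#' @param noise_placement `"additive"` adds observation noise after the
#'   coefficient/amplitude scaling (default); `"pre_scaling"` adds it to the
#'   unit chirp before scaling.
#' @param seed RNG seed used by [generate_chirp_trials()] (default 1).
#'
#' @return An object of class `chirp_spec`.
#' @export
chirp_spec <- function(n_channels = 10, n_timepoints = 300, n_trials = 2000,
                       coeff_range = c(1, 4), freq_start = 2, freq_end = 30,
                       amp_start = 0.2, amp_end = 1, noise_sd = 0.5,
                       sampling_rate = 30, random_coeffs = FALSE,
                       noise_placement = c("additive", "pre_scaling"),
                       seed = 1) {
  spec <- list(n_channels = as.integer(n_channels),
               n_timepoints = as.integer(n_timepoints),
               n_trials = as.integer(n_trials),
               coeff_range = as.numeric(coeff_range),
               freq_start = freq_start, freq_end = freq_end,
               amp_start = amp_start, amp_end = amp_end,
               noise_sd = noise_sd, sampling_rate = sampling_rate,
               random_coeffs = isTRUE(random_coeffs),
               noise_placement = match.arg(noise_placement),
               seed = as.integer(seed))
  class(spec) <- "chirp_spec"
  validate_chirp_spec(spec)
  spec
}

validate_chirp_spec <- function(spec) {
  fail <- function(field, msg)
    stop("invalid chirp spec: `", field, "` ", msg, call. = FALSE)
  if (spec$n_channels < 1L) fail("n_channels", "must be >= 1")
  if (spec$n_timepoints < 2L) fail("n_timepoints", "must be >= 2")
  if (spec$n_trials < 2L || spec$n_trials %% 2L != 0L)
    fail("n_trials", "must be even and >= 2 (balanced classes)")
  if (length(spec$coeff_range) != 2L || spec$coeff_range[1] <= 0)
    fail("coeff_range", "must be an interval with a positive lower bound")
  if (spec$coeff_range[2] <= spec$coeff_range[1])
    fail("coeff_range", "endpoints must be distinct and increasing (the channel coefficients must be distinct)")
  if (spec$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (spec$sampling_rate <= 0) fail("sampling_rate", "must be > 0")
  invisible(spec)
}

#' @export
print.chirp_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<chirp_spec> %d trials x %d time points x %d channels\n",
    "  coefficients in (%g, %g)%s; sweep %g -> %g cycles/trial;\n",
    "  amplitude %g -> %g; noise sd %g (%s); seed %d\n"),
    x$n_trials, x$n_timepoints, x$n_channels,
    x$coeff_range[1], x$coeff_range[2],
    if (x$random_coeffs) " (uniform draws)" else " (evenly spaced)",
    x$freq_start, x$freq_end, x$amp_start, x$amp_end,
    x$noise_sd, x$noise_placement, x$seed))
  invisible(x)
}

#' Generate simulated chirp trials with time-shuffled controls
#'
#' Draws a balanced [trial_set()] according to a [chirp_spec()].  Every trial
#' starts as a behavior-style draw: channel `r` carries
#' `coeff_r * amp(t) * sin(phase(t))` where the instantaneous frequency sweeps
#' linearly from `freq_start` to `freq_end` cycles per trial and the amplitude
#' ramps linearly from `amp_start` to `amp_end`, with an independent random
#' initial phase per trial and additive Gaussian noise.  The control half is
#' then time-shuffled: one random permutation of the time indices per trial,
#' applied jointly to all channels.  The permutations are stored in
#' `meta$control_perms` so each control trial can be un-shuffled exactly.
#'
#' @param spec A [chirp_spec()].
#' @return A [trial_set()] with `n_trials` trials (first half 'behavior',
#'   second half 'control'), `t_zero_index` at the last time point, and
#'   `meta` containing the spec, the channel coefficients, and the control
#'   permutations.
#' @examples
#' ts <- generate_chirp_trials(chirp_spec(n_trials = 20, n_timepoints = 50,
#'                                        seed = 7))
#' dim(ts)
#' @export
generate_chirp_trials <- function(spec) {
  stopifnot(inherits(spec, "chirp_spec"))
  validate_chirp_spec(spec)
  n <- spec$n_trials; T <- spec$n_timepoints; R <- spec$n_channels
  set.seed(spec$seed)

  lo <- spec$coeff_range[1]; hi <- spec$coeff_range[2]
  coeffs <- if (spec$random_coeffs) {
    cf <- runif(R, lo, hi)
    while (anyDuplicated(cf)) cf <- runif(R, lo, hi)
    cf
  } else {
    lo + (hi - lo) * seq_len(R) / (R + 1)  # evenly spaced, open interval
  }

  s <- (seq_len(T) - 1) / (T - 1)
  phase0 <- 2 * pi * (spec$freq_start * s +
                      0.5 * (spec$freq_end - spec$freq_start) * s^2)
  amp <- spec$amp_start + (spec$amp_end - spec$amp_start) * s

  theta <- runif(n, 0, 2 * pi)
  noise <- array(rnorm(n * T * R, sd = spec$noise_sd), dim = c(n, T, R))

  X <- array(0, dim = c(n, T, R))
  base <- sin(outer(theta, phase0, "+"))       # n x T unit chirps
  for (r in seq_len(R)) {
    if (spec$noise_placement == "additive") {
      X[, , r] <- sweep(base, 2, coeffs[r] * amp, "*") + noise[, , r]
    } else {
      X[, , r] <- sweep(base + noise[, , r], 2, coeffs[r] * amp, "*")
    }
  }

  n_beh <- n %/% 2L
  ctrl <- seq.int(n_beh + 1L, n)
  perms <- t(vapply(ctrl, function(i) sample.int(T), integer(T)))
  for (j in seq_along(ctrl))
    X[ctrl[j], , ] <- X[ctrl[j], perms[j, ], ]

  labels <- c(rep(1L, n_beh), rep(0L, n - n_beh))
  trial_set(X, labels,
            sampling_rate = spec$sampling_rate,
            t_zero_index = T,
            channel_names = sprintf("ch%02d", seq_len(R)),
            meta = list(spec = unclass(spec), coefficients = coeffs,
                        control_perms = perms, control_index = ctrl))
}

#' Class-averaged short-time Fourier transform magnitude
#'
#' The distribution-shift diagnostic: the STFT magnitude of one channel,
#' averaged across the trials of one class.  For the chirp data this shows
#' the ridge moving from low to high frequency and the magnitude growing
#' with the amplitude ramp.
#'
#' @param x A [trial_set()].
#' @param channel Channel index.
#' @param window_len STFT window length in time points (default 64, capped
#'   at the trial length).
#' @param hop Hop between consecutive frames in time points (default
#'   `window_len %/% 4`).
#' @param class Which class to average over (default 1, 'behavior').
#' @return An object of class `stft_magnitude`: list with `magnitude`
#'   (frequency x frames), `freq` (cycles per second), `times` (frame
#'   centres, seconds from trial start), `channel`, `class`.
#' @export
stft_magnitude <- function(x, channel, window_len = 64,
                           hop = max(1L, window_len %/% 4L), class = 1) {
  stopifnot(inherits(x, "trial_set"))
  R <- dim(x$data)[3L]; T <- dim(x$data)[2L]
  channel <- as.integer(channel)
  if (channel < 1L || channel > R)
    stop("channel index ", channel, " out of range [1, ", R, "]", call. = FALSE)
  if (window_len > T) stop("window_len must be <= n_timepoints", call. = FALSE)
  if (hop < 1L) stop("hop must be >= 1", call. = FALSE)
  idx <- which(x$labels == class)
  if (!length(idx)) stop("no trials of class ", class, call. = FALSE)
  acc <- NULL
  for (i in idx) {
    sg <- signal::specgram(x$data[i, , channel], n = window_len,
                           Fs = x$sampling_rate,
                           overlap = window_len - hop)
    m <- Mod(sg$S)
    acc <- if (is.null(acc)) m else acc + m
  }
  structure(list(magnitude = acc / length(idx),
                 freq = as.numeric(sg$f), times = as.numeric(sg$t),
                 channel = channel, class = class),
            class = "stft_magnitude")
}

#' @export
print.stft_magnitude <- function(x, ...) {
  cat(sprintf("<stft_magnitude> channel %d, class %d: %d frequency bins x %d frames\n",
              x$channel, x$class, nrow(x$magnitude), ncol(x$magnitude)))
  invisible(x)
}

#' @export
plot.stft_magnitude <- function(x, ...) {
  image(x$times, x$freq, t(x$magnitude), xlab = "time (s)",
        ylab = "frequency (Hz)", main = "STFT magnitude", ...)
  invisible(x)
}
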