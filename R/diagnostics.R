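# Gradient-stability diagnostics and classification-mechanism analyses.
# During backpropagation through time the gradient reaching time t' from
# time t is proportional to the product of recurrent weight matrices over
# the horizon t - t'; the growth/decay rate of that product's norm (its
# Lyapunov exponent) governs exploding/vanishing gradients.  A static RNN
# multiplies the same matrix repeatedly; a time-varying RNN multiplies
# different draws, which slows the exponential drift.  The induced 1-norm
# (maximum absolute column sum) is used throughout: it is submultiplicative,
# which is what the comparison argument needs.

norm1 <- function(M) max(colSums(abs(M)))

#' Norms of recurrent Jacobian products over increasing horizons
#'
#' For a static matrix the product over horizon `h` is the matrix power
#' `W^h`; for a list of window matrices the factor at step `j` is the matrix
#' of window `ceiling(j / window_size)`.  The Lyapunov exponent is estimated
#' both as the least-squares slope of log-norm against horizon and as the
#' single largest-horizon quotient.
#'
#' @param W A square matrix (static recurrence) or a list of square matrices
#'   (one per window).
#' @param horizons Integer horizons to evaluate (default `1:50`).
#' @param window_size Steps per window when `W` is a list (default 1).
#' @return Object of class `jacobian_product_summary`: `log_norms`
#'   (data.frame of horizon and log induced-1 norm), `lambda` (slope
#'   estimate), `lambda_quotient`, `kind`, and `spectral_radius` (static
#'   case only).
#' @export
jacobian_product_norms <- function(W, horizons = 1:50, window_size = 1) {
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < 1L)) stop("horizons must be >= 1", call. = FALSE)
  static <- !is.list(W)
  Ws <- if (static) list(as.matrix(W)) else lapply(W, as.matrix)
  for (M in Ws)
    if (nrow(M) != ncol(M)) stop("matrices must be square", call. = FALSE)
  hmax <- max(horizons)
  n_need <- ceiling(hmax / window_size)
  if (!static && length(Ws) < n_need)
    stop("need ", n_need, " window matrices for horizon ", hmax, call. = FALSE)
  P <- diag(nrow(Ws[[1]]))
  logn <- numeric(length(horizons)); hi <- 1L
  for (j in seq_len(hmax)) {
    M <- if (static) Ws[[1]] else Ws[[ceiling(j / window_size)]]
    P <- M %*% P
    if (hi <= length(horizons) && horizons[hi] == j) {
      logn[hi] <- log(norm1(P)); hi <- hi + 1L
    }
  }
  lambda <- if (length(horizons) > 1L)
    unname(coef(stats::lm(logn ~ horizons))[2]) else logn / horizons
  structure(list(
    log_norms = data.frame(horizon = horizons, log_norm = logn),
    lambda = lambda,
    lambda_quotient = logn[length(logn)] / horizons[length(horizons)],
    kind = if (static) "static" else "time-varying",
    spectral_radius = if (static) max(Mod(eigen(Ws[[1]],
                                                only.values = TRUE)$values))
                      else NA_real_,
    norm = "induced-1"),
    class = "jacobian_product_summary")
}

#' @export
print.jacobian_product_summary <- function(x, ...) {
  cat(sprintf("<jacobian_product_summary> %s weights, horizons %d..%d (induced 1-norm)\n",
              x$kind, min(x$log_norms$horizon), max(x$log_norms$horizon)))
  cat(sprintf("  Lyapunov exponent: slope %.4f, quotient %.4f%s\n",
              x$lambda, x$lambda_quotient,
              if (!is.na(x$spectral_radius))
                sprintf("; spectral radius %.4f", x$spectral_radius) else ""))
  invisible(x)
}

#' Monte-Carlo comparison of static and time-varying gradient products
#'
#' Draws a static recurrent matrix and a set of window matrices i.i.d. from
#' the same Gaussian ensemble, computes the log induced-1 norm of the
#' gradient product over a horizon for both, and tests one-sided whether the
#' time-varying products grow more slowly in expectation.
#'
#' @param n_hidden Matrix dimension (default 32).
#' @param sd Entry standard deviation (default `1.2 / sqrt(n_hidden)`, a
#'   mildly super-critical ensemble).
#' @param horizon Product length (default 50).
#' @param n_draws Monte-Carlo draws (default 200, minimum 30).
#' @param window_size Steps per window matrix on the time-varying side
#'   (default 1: a fresh matrix every step).
#' @param seed Optional RNG seed.
#' @param fixed_matrix If supplied, every factor on both sides is this
#'   matrix (degenerate ensemble; the two log-norms then agree exactly).
#' @return Object of class `gradient_inequality`: per-draw log-norms,
#'   their means, and the one-sided Welch p-value for
#'   `mean(log ||J_TV||) < mean(log ||J_static||)`.
#' @export
gradient_inequality_experiment <- function(n_hidden = 32,
                                           sd = 1.2 / sqrt(n_hidden),
                                           horizon = 50, n_draws = 200,
                                           window_size = 1, seed = NULL,
                                           fixed_matrix = NULL) {
  if (n_draws < 30) stop("n_draws must be >= 30", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_win <- ceiling(horizon / window_size)
  draw <- function() matrix(rnorm(n_hidden^2, sd = sd), n_hidden, n_hidden)
  log_static <- numeric(n_draws); log_tv <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    Wstat <- fixed_matrix %||% draw()
    wins <- if (is.null(fixed_matrix)) replicate(n_win, draw(),
                                                 simplify = FALSE)
            else rep(list(fixed_matrix), n_win)
    log_static[i] <- jacobian_product_norms(
      Wstat, horizons = horizon)$log_norms$log_norm
    log_tv[i] <- jacobian_product_norms(
      wins, horizons = horizon,
      window_size = window_size)$log_norms$log_norm
  }
  p <- if (sd(log_tv - log_static) == 0) {
    if (mean(log_tv) < mean(log_static)) 0 else 1
  } else t.test(log_tv, log_static, alternative = "less")$p.value
  structure(list(log_norm_tv = log_tv, log_norm_static = log_static,
                 mean_tv = mean(log_tv), mean_static = mean(log_static),
                 p_value = p, horizon = horizon, n_draws = n_draws,
                 window_size = window_size, sd = sd, n_hidden = n_hidden),
            class = "gradient_inequality")
}

#' @export
print.gradient_inequality <- function(x, ...) {
  cat(sprintf("<gradient_inequality> horizon %d, %d draws (N = %d, sd = %.4g)\n",
              x$horizon, x$n_draws, x$n_hidden, x$sd))
  cat(sprintf("  mean log||J||: time-varying %.3f vs static %.3f (one-sided p = %.3g)\n",
              x$mean_tv, x$mean_static, x$p_value))
  invisible(x)
}

#' Pairwise distances between the learnt window weights
#'
#' Frobenius (Euclidean) distances between the input, recurrent and output
#' weights of every pair of windows; bright off-diagonal bands indicate
#' where along the trial the learnt weights change sharply.
#'
#' @param tv A [tv_weights()] bundle or fitted [tvrnn()] (>= 2 windows).
#' @return Object of class `weight_distance_map`: list of three symmetric
#'   `[windows x windows]` matrices `input`, `recurrent`, `output`.
#' @export
weight_distance_map <- function(tv) {
  if (inherits(tv, "tvrnn")) tv <- tv$weights
  stopifnot(inherits(tv, "tv_weights"))
  if (length(tv$windows) < 2L) stop("need >= 2 windows", call. = FALSE)
  pair_dist <- function(get) {
    V <- t(vapply(tv$windows, function(w) as.numeric(get(w)),
                  numeric(length(get(tv$windows[[1]])))))
    as.matrix(dist(V))
  }
  structure(list(input = pair_dist(function(w) w$W_x),
                 recurrent = pair_dist(function(w) w$W_h),
                 output = pair_dist(function(w) w$w_y)),
            class = "weight_distance_map")
}

#' @export
print.weight_distance_map <- function(x, ...) {
  K <- nrow(x$input)
  cat(sprintf("<weight_distance_map> %d windows; mean off-diagonal distance: input %.3f, recurrent %.3f, output %.3f\n",
              K, mean(x$input[upper.tri(x$input)]),
              mean(x$recurrent[upper.tri(x$recurrent)]),
              mean(x$output[upper.tri(x$output)])))
  invisible(x)
}

#' @export
plot.weight_distance_map <- function(x, which = "recurrent", ...) {
  M <- x[[match.arg(which, c("input", "recurrent", "output"))]]
  image(seq_len(nrow(M)), seq_len(ncol(M)), M, xlab = "window",
        ylab = "window", main = paste("weight distance:", which), ...)
  invisible(x)
}

#' Class-conditional output trajectories
#'
#' Mean and standard deviation of the per-time-point output `y_t` for each
#' class, with a divergence time: the earliest time at which the class means
#' differ by more than `sd_multiplier` times the pooled standard deviation.
#'
#' @param model A fitted [tvrnn()]/[causal_transformer()] (then `x` must be
#'   a labelled [trial_set()]), or an `output_trajectory`/probability matrix
#'   (then `labels` is required).
#' @param x Trials to evaluate (ignored when `model` is already an output).
#' @param labels Binary labels when `model` is an output.
#' @param sd_multiplier Divergence threshold in pooled-sd units (default 1).
#' @return Object of class `output_trajectories`: `mean` and `sd`
#'   (`2 x T`, rows control/behavior), `divergence_index` (NA if the means
#'   never separate), `n_per_class`.
#' @export
output_trajectories <- function(model, x = NULL, labels = NULL,
                                sd_multiplier = 1) {
  if (inherits(model, c("tvrnn", "causal_transformer"))) {
    stopifnot(inherits(x, "trial_set"))
    Y <- predict(model, x)
    labels <- x$labels
  } else {
    Y <- if (inherits(model, "output_trajectory")) model$y else as.matrix(model)
    if (is.null(labels)) stop("labels are required", call. = FALSE)
  }
  stopifnot(nrow(Y) == length(labels))
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("each class needs at least one trial", call. = FALSE)
  m <- rbind(control = colMeans(Y[labels == 0L, , drop = FALSE]),
             behavior = colMeans(Y[labels == 1L, , drop = FALSE]))
  s <- rbind(control = apply(Y[labels == 0L, , drop = FALSE], 2, sd),
             behavior = apply(Y[labels == 1L, , drop = FALSE], 2, sd))
  s[is.na(s)] <- 0
  pooled <- sqrt((s[1, ]^2 + s[2, ]^2) / 2)
  gap <- abs(m[2, ] - m[1, ])
  div <- which(gap > sd_multiplier * pooled)
  structure(list(mean = m, sd = s,
                 divergence_index = if (length(div)) div[1L] else NA_integer_,
                 sd_multiplier = sd_multiplier,
                 n_per_class = c(control = n0, behavior = n1)),
            class = "output_trajectories")
}

#' @export
print.output_trajectories <- function(x, ...) {
  cat(sprintf("<output_trajectories> %d control / %d behavior trials over %d time points\n",
              x$n_per_class[1], x$n_per_class[2], ncol(x$mean)))
  cat(sprintf("  class means diverge (> %g pooled sd) at index %s\n",
              x$sd_multiplier, x$divergence_index))
  invisible(x)
}

#' @export
plot.output_trajectories <- function(x, ...) {
  Tn <- ncol(x$mean)
  matplot(seq_len(Tn), t(x$mean), type = "l", lty = 1, col = c(4, 2),
          ylim = c(0, 1), xlab = "time point", ylab = "output y_t", ...)
  abline(h = 0.5, lty = 2)
  if (!is.na(x$divergence_index)) abline(v = x$divergence_index, lty = 3)
  legend("topleft", rownames(x$mean), col = c(4, 2), lty = 1, bty = "n")
  invisible(x)
}
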