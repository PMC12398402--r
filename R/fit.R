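#' Fit a (time-varying) recurrent classifier by backpropagation through time
#'
#' The single fitting entry point for the recurrent models.  `strategy`
#' selects both the architecture and the loss:
#' \describe{
#'   \item{`"S1"`}{standard RNN (one weight bundle for the whole sequence),
#'     binary cross-entropy on the final output only.}
#'   \item{`"S2"`}{standard RNN, cross-entropy aggregated over every time
#'     point (mean over time).}
#'   \item{`"TV"`}{time-varying RNN: an independent weight bundle per window
#'     of `window_size` time points, hidden state carried continuously across
#'     windows, all bundles optimised jointly (end-to-end) in every batch
#'     under the all-step loss.}
#' }
#' Optimisation is Adam on mini-batches, in single precision, with the epoch
#' of lowest validation loss kept as the checkpoint.  Gradients of an example
#' recurrent weight per window are recorded every epoch as a
#' vanishing/exploding-gradient diagnostic.
#'
#' @param x A [trial_set()], or a `[trials x time x channels]` array (then
#'   `y` is required).
#' @param y Binary labels, one per trial (ignored when `x` is a trial set).
#' @param strategy `"TV"`, `"S1"` or `"S2"` (see above).
#' @param window_size Window length `w` for `strategy = "TV"` (default 30,
#'   capped at the sequence length).  Ignored otherwise (a single window
#'   spans the sequence).
#' @param n_hidden Hidden units per window (default 64).
#' @param epochs Training epochs (default 1000).  `epochs = 0` returns the
#'   initialisation unchanged.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 64).
#' @param validation Either a fraction in (0,1) of trials held out for
#'   validation (stratified; default 0.2), an integer vector of trial
#'   indices, or `NULL`/0 for no validation monitoring.
#' @param seed RNG seed controlling initialisation, the validation split and
#'   batch shuffling.  Two runs with identical configuration and seed are
#'   identical.
#' @param warm_start For `strategy = "TV"`: `TRUE` to first train a static
#'   S1 model with the same configuration and initialise every window from
#'   it, or a fitted static `tvrnn` object to copy from (default `FALSE`:
#'   independent random initialisation per window).
#' @param record_gradients Record the per-epoch gradient trace
#'   (default `TRUE`).
#' @param grad_vanish_tol,grad_explode_tol Magnitude thresholds used only to
#'   flag entries of the gradient trace (defaults 1e-7 and 1e2).
#' @param verbose Print a progress line every 50 epochs.
#'
#' @return An object of class `tvrnn` with components `weights` (the
#'   checkpointed [tv_weights()]), `final_weights`, `history` (per-epoch
#'   train/validation loss and validation accuracy), `gradient_trace`,
#'   `checkpoint_epoch`, and the fitting configuration.  Methods:
#'   [predict.tvrnn()], `print`, `summary`, `coef`, `plot`, `fitted`,
#'   `residuals`.
#' @seealso [tvrnn_cv()] for cross-validated fitting,
#'   [causal_transformer()] for the attention baseline.
#' @export
tvrnn <- function(x, y = NULL, strategy = c("TV", "S1", "S2"),
                  window_size = NULL, n_hidden = 64, epochs = 1000,
                  learning_rate = 1e-4, batch_size = 64, validation = 0.2,
                  seed = 1, warm_start = FALSE, record_gradients = TRUE,
                  grad_vanish_tol = 1e-7, grad_explode_tol = 1e2,
                  verbose = FALSE) {
  strategy <- match.arg(strategy)
  X <- as_input_array(x)
  labels <- if (inherits(x, "trial_set")) x$labels else as.integer(y)
  if (is.null(labels)) stop("labels `y` are required", call. = FALSE)
  stopifnot(length(labels) == dim(X)[1L], all(labels %in% c(0L, 1L)))
  n <- dim(X)[1L]; T <- dim(X)[2L]; R <- dim(X)[3L]
  if (epochs < 0 || learning_rate <= 0)
    stop("epochs must be >= 0 and learning_rate > 0", call. = FALSE)

  w <- if (strategy == "TV") {
    ws <- as.integer(window_size %||% min(30L, T))
    if (ws < 1L) stop("window_size must be >= 1", call. = FALSE)
    min(ws, T)
  } else T
  n_win <- ceiling(T / w)
  win_assign <- window_assignment(T, w)
  lw <- loss_weights_for(if (strategy == "S1") "S1" else "S2", T)

  # warm start: a static fit to clone into every window
  warm_fit <- NULL
  if (inherits(warm_start, "tvrnn")) {
    warm_fit <- warm_start
  } else if (isTRUE(warm_start) && strategy == "TV") {
    warm_fit <- tvrnn(x, y, strategy = "S1", n_hidden = n_hidden,
                      epochs = epochs, learning_rate = learning_rate,
                      batch_size = batch_size, validation = validation,
                      seed = seed, record_gradients = FALSE)
  }

  set.seed(seed)
  windows <- if (!is.null(warm_fit)) {
    if (length(warm_fit$weights$windows) != 1L)
      stop("warm_start must be a static (single-window) fit", call. = FALSE)
    rep(list(unclass(warm_fit$weights$windows[[1]])), n_win)
  } else {
    lapply(seq_len(n_win), function(k)
      unclass(rnn_params(n_hidden, R)))
  }

  # validation split (stratified)
  if (is.null(validation) || identical(validation, 0)) {
    val_idx <- integer(0)
  } else if (length(validation) == 1L && validation > 0 && validation < 1) {
    val_idx <- sort(unlist(lapply(unique(labels), function(cl) {
      pool <- which(labels == cl)
      sample(pool, round(validation * length(pool)))
    }), use.names = FALSE))
  } else {
    val_idx <- sort(as.integer(validation))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  has_val <- length(val_idx) > 0L
  if (has_val) {
    Xval <- X[val_idx, , , drop = FALSE]
    yval <- labels[val_idx]
  }

  # Adam state
  pnames <- c("W_x", "W_h", "w_y", "b_h", "b_y")
  zero_like <- function(win) lapply(win[pnames], function(p) p * 0)
  mst <- lapply(windows, zero_like)
  vst <- lapply(windows, zero_like)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  step <- 0L

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  gtrace <- NULL
  best_val <- Inf; best_windows <- windows; best_epoch <- NA_integer_

  for (ep in seq_len(epochs)) {
    perm <- sample(train_idx)
    nb <- ceiling(length(perm) / batch_size)
    ep_loss <- 0; seen <- 0
    gsum <- numeric(n_win)
    for (b in seq_len(nb)) {
      batch <- perm[((b - 1L) * batch_size + 1L):min(b * batch_size, length(perm))]
      res <- .cpp_train_grad(X[batch, , , drop = FALSE], labels[batch],
                             windows, win_assign, lw)
      if (!is.finite(res$loss)) {
        stop(sprintf(paste0(
          "training diverged (non-finite loss) at epoch %d; last recorded ",
          "recurrent gradients: %s"), ep,
          paste(sprintf("%.3g", gsum / max(b - 1, 1)), collapse = ", ")),
          call. = FALSE)
      }
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (k in seq_len(n_win)) {
        g <- res$grads[[k]]
        for (pn in pnames) {
          mst[[k]][[pn]] <- b1 * mst[[k]][[pn]] + (1 - b1) * g[[pn]]
          vst[[k]][[pn]] <- b2 * vst[[k]][[pn]] + (1 - b2) * g[[pn]]^2
          windows[[k]][[pn]] <- windows[[k]][[pn]] -
            learning_rate * corr * mst[[k]][[pn]] /
            (sqrt(vst[[k]][[pn]]) + aeps)
        }
        gsum[k] <- gsum[k] + g$W_h[1L, 1L]
      }
      ep_loss <- ep_loss + res$loss * length(batch)
      seen <- seen + length(batch)
    }
    ep_loss <- ep_loss / seen

    val_loss <- NA_real_; val_acc <- NA_real_
    if (has_val) {
      Yv <- .cpp_forward_f(Xval, windows, win_assign)
      val_loss <- if (strategy == "S1") loss_s1(Yv, yval) else loss_s2(Yv, yval)
      val_acc <- mean(as.integer(Yv[, T] >= 0.5) == yval)
      if (val_loss < best_val) {
        best_val <- val_loss; best_windows <- windows; best_epoch <- ep
      }
    }
    history[ep, ] <- list(ep, ep_loss, val_loss, val_acc)

    if (record_gradients) {
      gmean <- gsum / nb
      gtrace <- rbind(gtrace, data.frame(
        epoch = ep, window = seq_len(n_win), grad = gmean,
        flag = ifelse(abs(gmean) < grad_vanish_tol, "vanishing",
                      ifelse(abs(gmean) > grad_explode_tol, "exploding",
                             "ok"))))
    }
    if (verbose && (ep %% 50L == 0L || ep == epochs))
      message(sprintf("epoch %d/%d: train %.4f, val %.4f", ep, epochs,
                      ep_loss, val_loss))
  }

  if (!has_val || is.na(best_epoch)) { best_windows <- windows; best_epoch <- epochs }
  mk <- function(ws) tv_weights(lapply(ws, function(p) structure(p, class = "rnn_params")),
                                window_size = w, n_timepoints = T)
  wt_best <- mk(best_windows)
  fitted_final <- .cpp_forward_f(X[train_idx, , , drop = FALSE],
                                 best_windows, win_assign)[, T]

  structure(list(
    weights = wt_best,
    final_weights = mk(windows),
    strategy = strategy, window_size = w, n_windows = n_win,
    n_timepoints = T, n_hidden = as.integer(n_hidden), n_channels = R,
    epochs = epochs, learning_rate = learning_rate, batch_size = batch_size,
    seed = seed, warm_started = !is.null(warm_fit),
    history = history, gradient_trace = gtrace,
    checkpoint_epoch = best_epoch, best_val_loss = best_val,
    train_index = train_idx, validation_index = val_idx,
    fitted_final = fitted_final, train_labels = labels[train_idx],
    sampling_rate = if (inherits(x, "trial_set")) x$sampling_rate else NA_real_,
    t_zero_index = if (inherits(x, "trial_set")) x$t_zero_index else T,
    call = match.call()),
    class = "tvrnn")
}

#' Predict per-time-point class probabilities from a fitted model
#'
#' @param object A fitted [tvrnn()] model.
#' @param newdata A [trial_set()] or `[trials x time x channels]` array with
#'   the same time and channel dimensions as the training data.
#' @param type `"prob"` (default) for the `[trials x time]` probability
#'   matrix, `"class"` for thresholded 0/1 calls, `"trajectory"` for the full
#'   `output_trajectory` (with hidden states).
#' @param which `"best"` (validation checkpoint, default) or `"final"`
#'   (last epoch) weights.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.tvrnn <- function(object, newdata,
                          type = c("prob", "class", "trajectory"),
                          which = c("best", "final"), ...) {
  type <- match.arg(type); which <- match.arg(which)
  wt <- if (which == "best") object$weights else object$final_weights
  tr <- tvrnn_forward(wt, newdata, keep_hidden = (type == "trajectory"))
  switch(type, prob = tr$y, class = tr$class_calls, trajectory = tr)
}

#' @export
print.tvrnn <- function(x, ...) {
  cat(sprintf("<tvrnn> strategy %s: %d window(s) of size %d, N = %d, T = %d, R = %d\n",
              x$strategy, x$n_windows, x$window_size, x$n_hidden,
              x$n_timepoints, x$n_channels))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs (lr %g, batch %d); final train loss %.4f",
                x$epochs, x$learning_rate, x$batch_size, last$train_loss))
    if (!is.na(last$val_loss))
      cat(sprintf("; checkpoint at epoch %d (val loss %.4f, val acc %.3f)",
                  x$checkpoint_epoch, x$best_val_loss,
                  x$history$val_accuracy[x$checkpoint_epoch]))
    cat("\n")
  } else cat("  untrained (epochs = 0)\n")
  invisible(x)
}

#' @export
summary.tvrnn <- function(object, ...) {
  print(object)
  if (!is.null(object$gradient_trace)) {
    tab <- table(object$gradient_trace$flag)
    cat("  gradient trace flags:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  n_par <- object$n_windows *
    (object$n_hidden * (object$n_hidden + object$n_channels + 2L) + 1L)
  cat(sprintf("  parameters: %d across %d window(s)\n", n_par,
              object$n_windows))
  invisible(object)
}

#' @export
coef.tvrnn <- function(object, which = c("best", "final"), ...) {
  which <- match.arg(which)
  if (which == "best") object$weights else object$final_weights
}

#' @export
fitted.tvrnn <- function(object, ...) object$fitted_final

#' @export
residuals.tvrnn <- function(object, ...)
  object$train_labels - object$fitted_final

#' @export
plot.tvrnn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history to plot"); return(invisible(x)) }
  rng <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", ylim = rng, xlab = "epoch",
       ylab = "loss", main = sprintf("tvrnn training (%s)", x$strategy), ...)
  if (any(!is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, lty = 2)
    abline(v = x$checkpoint_epoch, col = "grey", lty = 3)
    legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Cross-validated fit and test-set predictions
#'
#' Fits one model per fold of a stratified K-fold split and collects the
#' held-out per-time-point predictions, the replicate structure all temporal
#' metrics are computed from.
#'
#' @param x A [trial_set()].
#' @param K Number of folds (default 5).
#' @param validation_rate Fraction of each fold's non-test trials used for
#'   validation (default 0.2).
#' @param seed Seed for the split; fold `k` is fitted with `seed + k - 1`.
#' @param keep_fits Keep the per-fold `tvrnn` objects (default `FALSE`;
#'   weights are large).
#' @param ... Passed on to [tvrnn()] (`strategy`, `window_size`, `epochs`,
#'   ...).
#' @return Object of class `tvrnn_cv`: list with `predictions` (per-fold
#'   `[n_test x T]` probability matrices), `labels` (per-fold test labels),
#'   `splits`, `time_seconds`, `chance_level`, and the call.
#' @export
tvrnn_cv <- function(x, K = 5, validation_rate = 0.2, seed = 1,
                     keep_fits = FALSE, ...) {
  stopifnot(inherits(x, "trial_set"))
  n <- dim(x$data)[1L]
  splits <- make_cv_splits(n, x$labels, K = K,
                           validation_rate = validation_rate, seed = seed)
  preds <- vector("list", K); labs <- vector("list", K)
  fits <- if (keep_fits) vector("list", K) else NULL
  for (k in seq_len(K)) {
    f <- splits$folds[[k]]
    xs <- x[c(f$train, f$validation)]
    val_pos <- if (length(f$validation))
      length(f$train) + seq_along(f$validation) else NULL
    fit <- tvrnn(xs, validation = val_pos, seed = seed + k - 1L, ...)
    preds[[k]] <- predict(fit, x[f$test])
    labs[[k]] <- x$labels[f$test]
    if (keep_fits) fits[[k]] <- fit
  }
  structure(list(predictions = preds, labels = labs, splits = splits,
                 fits = fits, time_seconds = time_axis(x),
                 chance_level = max(mean(x$labels == 1L),
                                    mean(x$labels == 0L)),
                 t_zero_index = x$t_zero_index, call = match.call()),
            class = "tvrnn_cv")
}

#' @export
print.tvrnn_cv <- function(x, ...) {
  Tn <- ncol(x$predictions[[1]])
  final <- vapply(seq_along(x$predictions), function(k)
    mean(as.integer(x$predictions[[k]][, Tn] >= 0.5) == x$labels[[k]]),
    numeric(1))
  cat(sprintf("<tvrnn_cv> %d folds; final-time accuracy %.3f (per fold: %s)\n",
              length(x$predictions), mean(final),
              paste(sprintf("%.3f", final), collapse = ", ")))
  invisible(x)
}
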