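# Sliding-window baselines: the classical alternative to a single sequential
# model.  The trial is cut into contiguous windows and an independent
# classifier is fitted per window -- a standard RNN (started from a zero
# hidden state, so no information crosses windows) or an SVM on the
# flattened [time x channel] window.  Each window's accuracy is reported at
# the last time point of that window.

#' Fit independent per-window classifiers
#'
#' @param x A labelled [trial_set()] (training trials).
#' @param kind `"independent_rnn_s1"`, `"independent_rnn_s2"` (per-window
#'   RNNs under the final-step / all-step loss), `"svm_rbf"` or
#'   `"svm_linear"` (e1071 SVMs on the flattened window).
#' @param window_len Window length in time points (default 30); the last
#'   window is truncated if `window_len` does not divide `T`.
#' @param seed RNG seed (window `j` uses `seed + j - 1` for the RNN kinds).
#' @param ... For the RNN kinds, passed to [tvrnn()] (`epochs`,
#'   `n_hidden`, ...); for the SVM kinds, passed to [e1071::svm()].
#' @return Object of class `sliding_baseline`: per-window classifiers,
#'   window index ranges, and `window_end` (the time point each window's
#'   prediction is reported at).
#' @export
sliding_baseline <- function(x, kind = c("independent_rnn_s1",
                                         "independent_rnn_s2",
                                         "svm_rbf", "svm_linear"),
                             window_len = 30, seed = 1, ...) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "trial_set"))
  Tn <- dim(x$data)[2L]
  window_len <- as.integer(window_len)
  if (window_len < 1L || window_len > Tn)
    stop("window_len must be in [1, T]", call. = FALSE)
  starts <- seq(1L, Tn, by = window_len)
  windows <- lapply(starts, function(s) s:min(s + window_len - 1L, Tn))
  fits <- vector("list", length(windows))
  for (j in seq_along(windows)) {
    idx <- windows[[j]]
    Xw <- x$data[, idx, , drop = FALSE]
    if (kind %in% c("svm_rbf", "svm_linear")) {
      feat <- matrix(Xw, nrow = dim(Xw)[1L])  # [trials, len * channels]
      fits[[j]] <- e1071::svm(feat, factor(x$labels, levels = c(0, 1)),
                              kernel = if (kind == "svm_rbf") "radial"
                                       else "linear", ...)
    } else {
      fits[[j]] <- tvrnn(Xw, x$labels,
                         strategy = if (kind == "independent_rnn_s1") "S1"
                                    else "S2",
                         seed = seed + j - 1L, ...)
    }
  }
  structure(list(kind = kind, fits = fits, windows = windows,
                 window_end = vapply(windows, max, integer(1)),
                 window_len = window_len, n_timepoints = Tn),
            class = "sliding_baseline")
}

#' @export
print.sliding_baseline <- function(x, ...) {
  cat(sprintf("<sliding_baseline> %s: %d windows of length %d over T = %d\n",
              x$kind, length(x$fits), x$window_len, x$n_timepoints))
  invisible(x)
}

#' Per-window predictions of a sliding baseline
#'
#' @param object A [sliding_baseline()].
#' @param newdata A [trial_set()] or array with the training time/channel
#'   dimensions.
#' @param ... Unused.
#' @return `[trials x n_windows]` matrix of class probabilities (RNN kinds)
#'   or hard 0/1 calls (SVM kinds), each column reported at the time point
#'   `attr(, "window_end")[j]`, the last of window `j`.
#' @export
predict.sliding_baseline <- function(object, newdata, ...) {
  X <- as_input_array(newdata)
  out <- matrix(0, dim(X)[1L], length(object$fits))
  for (j in seq_along(object$fits)) {
    idx <- object$windows[[j]]
    Xw <- X[, idx, , drop = FALSE]
    out[, j] <- if (inherits(object$fits[[j]], "svm")) {
      as.numeric(as.character(
        predict(object$fits[[j]], matrix(Xw, nrow = dim(Xw)[1L]))))
    } else {
      p <- predict(object$fits[[j]], Xw)
      p[, ncol(p)]
    }
  }
  attr(out, "window_end") <- object$window_end
  out
}

# Cross-validated sliding baseline: per-fold window-end predictions in the
# same shape tvrnn_cv produces, so temporal_accuracy() applies unchanged
# (with the time axis restricted to window ends).
sliding_cv <- function(x, kind, window_len = 30, K = 5, seed = 1, ...) {
  splits <- make_cv_splits(dim(x$data)[1L], x$labels, K = K, seed = seed)
  preds <- vector("list", K); labs <- vector("list", K)
  ends <- NULL
  for (k in seq_len(K)) {
    f <- splits$folds[[k]]
    fit <- sliding_baseline(x[c(f$train, f$validation)], kind = kind,
                            window_len = window_len, seed = seed + k - 1L,
                            ...)
    preds[[k]] <- predict(fit, x[f$test])
    labs[[k]] <- x$labels[f$test]
    ends <- fit$window_end
  }
  structure(list(predictions = preds, labels = labs, splits = splits,
                 fits = NULL, time_seconds = time_axis(x)[ends],
                 chance_level = max(mean(x$labels == 1L),
                                    mean(x$labels == 0L)),
                 t_zero_index = length(ends), window_end = ends,
                 call = match.call()),
            class = "tvrnn_cv")
}
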