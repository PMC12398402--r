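# Evaluation metrics for temporal decoding: per-time-point cross-validated
# accuracy, area under the accuracy curve above chance, and the earliest
# decoding time under one-tailed tests with Benjamini-Hochberg correction.

#' Per-time-point classification accuracy across folds
#'
#' For each fold and each time point, predictions are thresholded at 0.5
#' (ties to class 1) and accuracy is computed as
#' `(TP + TN) / (TP + TN + FP + FN)`; the reported curve is the mean over
#' folds.
#'
#' @param predictions A [tvrnn_cv()] object, or a list of per-fold
#'   `[trials x time]` probability matrices.
#' @param labels List of per-fold binary label vectors (taken from the
#'   `tvrnn_cv` object if given).
#' @param chance_level Expected accuracy of an uninformed classifier; default
#'   is the pooled majority-class fraction (0.5 for balanced classes).
#' @param time_seconds Time axis in seconds relative to behavior onset; by
#'   default time-point indices are used.
#' @param t_zero_index Index of behavior onset (default: last time point).
#' @return Object of class `temporal_accuracy_curve`: `accuracy` (length
#'   `T`), `per_fold` (`K x T`), `confusion` (`K x T x 4`, TP/TN/FP/FN),
#'   `chance_level`, `time_seconds`, `t_zero_index`.
#' @export
temporal_accuracy <- function(predictions, labels = NULL, chance_level = NULL,
                              time_seconds = NULL, t_zero_index = NULL) {
  if (inherits(predictions, "tvrnn_cv")) {
    cv <- predictions
    labels <- cv$labels
    time_seconds <- time_seconds %||% cv$time_seconds
    t_zero_index <- t_zero_index %||% cv$t_zero_index
    predictions <- cv$predictions
  }
  stopifnot(is.list(predictions), is.list(labels),
            length(predictions) == length(labels))
  K <- length(predictions)
  if (K < 2L) stop("need >= 2 folds", call. = FALSE)
  Tn <- ncol(predictions[[1]])
  per_fold <- matrix(NA_real_, K, Tn)
  confusion <- array(0L, dim = c(K, Tn, 4L),
                     dimnames = list(NULL, NULL, c("TP", "TN", "FP", "FN")))
  pooled <- unlist(labels)
  for (k in seq_len(K)) {
    p <- predictions[[k]]; yk <- labels[[k]]
    if (!nrow(p) || !length(yk)) stop("empty fold ", k, call. = FALSE)
    stopifnot(nrow(p) == length(yk), ncol(p) == Tn)
    calls <- p >= 0.5
    for (t in seq_len(Tn)) {
      tp <- sum(calls[, t] & yk == 1L); tn <- sum(!calls[, t] & yk == 0L)
      fp <- sum(calls[, t] & yk == 0L); fn <- sum(!calls[, t] & yk == 1L)
      confusion[k, t, ] <- c(tp, tn, fp, fn)
      per_fold[k, t] <- (tp + tn) / (tp + tn + fp + fn)
    }
  }
  structure(list(
    accuracy = colMeans(per_fold),
    per_fold = per_fold,
    confusion = confusion,
    chance_level = chance_level %||%
      max(mean(pooled == 1L), mean(pooled == 0L)),
    time_seconds = time_seconds %||% as.numeric(seq_len(Tn)),
    t_zero_index = as.integer(t_zero_index %||% Tn)),
    class = "temporal_accuracy_curve")
}

#' @export
print.temporal_accuracy_curve <- function(x, ...) {
  Tn <- length(x$accuracy)
  cat(sprintf(
    "<temporal_accuracy_curve> %d folds x %d time points; chance %.3f; final accuracy %.3f\n",
    nrow(x$per_fold), Tn, x$chance_level, x$accuracy[Tn]))
  invisible(x)
}

#' @export
plot.temporal_accuracy_curve <- function(x, ...) {
  matplot(x$time_seconds, t(x$per_fold), type = "l", lty = 3, col = "grey",
          xlab = "time (s, relative to onset)", ylab = "accuracy",
          ylim = c(0, 1), ...)
  lines(x$time_seconds, x$accuracy, lwd = 2)
  abline(h = x$chance_level, lty = 2)
  invisible(x)
}

#' Area under the accuracy curve above chance
#'
#' Trapezoidal integral of `accuracy - chance_level` over a time span, in
#' accuracy-seconds.  Excursions below chance are included (not clipped).
#'
#' @param curve A [temporal_accuracy()] curve.
#' @param t_start,t_end Span endpoints on the curve's time axis (seconds);
#'   defaults to the full curve.
#' @return Scalar AUAC.
#' @export
auac <- function(curve, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(curve, "temporal_accuracy_curve"))
  tt <- curve$time_seconds
  t_start <- t_start %||% tt[1]; t_end <- t_end %||% tt[length(tt)]
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  sel <- tt >= t_start & tt <= t_end
  if (sum(sel) < 2L) stop("span contains fewer than 2 time points", call. = FALSE)
  pracma::trapz(tt[sel], curve$accuracy[sel] - curve$chance_level)
}

#' Benjamini-Hochberg rejection calls
#'
#' Step-up false-discovery-rate control at level `alpha` (delegating to
#' `stats::p.adjust`).
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector of rejection calls.
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH") <= alpha
}

#' Earliest decoding time
#'
#' At every time point the per-fold accuracies are tested against chance
#' with a one-sample, one-tailed t-test (alternative: greater); p-values are
#' Benjamini-Hochberg corrected across time points.  The earliest decoding
#' time (EDT) is the earliest `t*` such that every time point from `t*` to
#' behavior onset is significant (up to `gap_tolerance` non-significant
#' gaps).  When the fold accuracies at a time point have zero variance the
#' t-statistic is undefined; the convention used is `p = 0` if their mean
#' exceeds chance and `p = 1` otherwise.
#'
#' @param curve A [temporal_accuracy()] curve (>= 2 folds).
#' @param alpha Significance level after correction (default 0.05).
#' @param gap_tolerance Maximum number of non-significant time points allowed
#'   inside `[t*, t_zero]` (default 0).
#' @return Object of class `early_decoding`: `p_values`, `significant`
#'   (BH-corrected calls), `edt_index`/`edt_seconds` (NA if never
#'   consistently significant), `onset_index`/`onset_seconds` (first
#'   significant time point, NA if none), and `auac` over the full curve.
#' @export
earliest_decoding_time <- function(curve, alpha = 0.05, gap_tolerance = 0L) {
  stopifnot(inherits(curve, "temporal_accuracy_curve"))
  acc <- curve$per_fold
  if (nrow(acc) < 2L) stop("need >= 2 folds for the t-test", call. = FALSE)
  Tn <- ncol(acc)
  ch <- curve$chance_level
  p <- vapply(seq_len(Tn), function(t) {
    a <- acc[, t]
    if (sd(a) == 0) return(if (mean(a) > ch) 0 else 1)
    t.test(a, mu = ch, alternative = "greater")$p.value
  }, numeric(1))
  sig <- benjamini_hochberg(p, alpha)
  tz <- curve$t_zero_index
  onset <- if (any(sig)) which(sig)[1L] else NA_integer_
  edt <- NA_integer_
  for (t0 in seq_len(tz)) {
    if (sum(!sig[t0:tz]) <= gap_tolerance) { edt <- t0; break }
  }
  structure(list(
    p_values = p, significant = sig, alpha = alpha,
    edt_index = edt,
    edt_seconds = if (is.na(edt)) NA_real_ else curve$time_seconds[edt],
    onset_index = onset,
    onset_seconds = if (is.na(onset)) NA_real_ else curve$time_seconds[onset],
    auac = auac(curve), chance_level = ch),
    class = "early_decoding")
}

#' @export
print.early_decoding <- function(x, ...) {
  cat(sprintf("<early_decoding> %d/%d time points significant (alpha %.3g, BH-corrected)\n",
              sum(x$significant), length(x$significant), x$alpha))
  cat(sprintf("  onset at index %s (%s s); EDT index %s (%s s); AUAC %.4f\n",
              x$onset_index, signif(x$onset_seconds, 4),
              x$edt_index, signif(x$edt_seconds, 4), x$auac))
  invisible(x)
}
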