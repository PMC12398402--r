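# Training losses.  Both strategies are binary cross-entropy against the
# trial label; they differ in which outputs they read: the final time point
# only (S1) or every time point (S2, aggregated by mean over time so the
# scale is comparable across sequence lengths).

bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Final-step cross-entropy loss (strategy S1)
#'
#' Binary cross-entropy of the last output `y_T` against the trial label,
#' averaged over trials.
#'
#' @param y An `output_trajectory` or `[trials x time]` probability matrix.
#' @param labels Binary labels, one per trial.
#' @return Scalar loss.
#' @export
loss_s1 <- function(y, labels) {
  m <- if (inherits(y, "output_trajectory")) y$y else y
  stopifnot(nrow(m) == length(labels), all(labels %in% c(0, 1)))
  bce(m[, ncol(m)], labels)
}

#' All-step cross-entropy loss (strategy S2)
#'
#' Binary cross-entropy of every output `y_t` against the trial label,
#' averaged over time points and trials.
#'
#' @inheritParams loss_s1
#' @return Scalar loss.  With `T = 1` this reduces exactly to [loss_s1()].
#' @export
loss_s2 <- function(y, labels) {
  m <- if (inherits(y, "output_trajectory")) y$y else y
  stopifnot(nrow(m) == length(labels), all(labels %in% c(0, 1)))
  mean(vapply(seq_len(ncol(m)), function(t) bce(m[, t], labels), numeric(1)))
}

loss_weights_for <- function(strategy, n_timepoints) {
  if (strategy == "S1") c(rep(0, n_timepoints - 1L), 1)
  else rep(1 / n_timepoints, n_timepoints)
}
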