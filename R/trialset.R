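#' Labelled multi-channel trial tensor
#'
#' A `trial_set` bundles a numeric array of trial-structured multi-channel
#' time series with a binary label per trial, a sampling rate, and the index
#' of behavior onset on the time axis.  It is the input container for every
#' model and metric in the package.
#'
#' @param data Numeric array `[trials x time x channels]` with no non-finite
#'   values.
#' @param labels Integer/numeric vector of 0/1 labels, one per trial
#'   (1 = 'behavior', 0 = 'control').
#' @param sampling_rate Time points per second (positive scalar).
#' @param t_zero_index Index (1-based) of behavior onset on the time axis.
#'   For simulated data this is the last time point: the class is decided by
#'   the whole sequence.
#' @param channel_names Optional character vector of channel names.
#' @param meta Optional list of provenance metadata (kept as-is).
#'
#' @return An object of class `trial_set`: a list with elements `data`,
#'   `labels`, `sampling_rate`, `t_zero_index`, `channel_names`, `meta`.
#' @seealso [generate_chirp_trials()], [read_trials()], [write_trials()]
#' @export
trial_set <- function(data, labels, sampling_rate = 30,
                      t_zero_index = dim(data)[2],
                      channel_names = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trials x time x channels]", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("`labels` must be binary (0/1)", call. = FALSE)
  if (length(labels) != dim(data)[1L])
    stop("length(labels) must equal the number of trials (dim(data)[1])",
         call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar", call. = FALSE)
  t_zero_index <- as.integer(t_zero_index)
  if (t_zero_index < 1L || t_zero_index > dim(data)[2L])
    stop("`t_zero_index` must lie on the time axis", call. = FALSE)
  if (!is.null(channel_names) && length(channel_names) != dim(data)[3L])
    stop("`channel_names` must have one entry per channel", call. = FALSE)
  structure(
    list(data = data, labels = labels, sampling_rate = sampling_rate,
         t_zero_index = t_zero_index, channel_names = channel_names,
         meta = meta),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> %d trials x %d time points x %d channels\n",
              d[1], d[2], d[3]))
  cat(sprintf("  labels: %d behavior / %d control; sampling rate %g Hz; t0 at index %d\n",
              sum(x$labels == 1L), sum(x$labels == 0L),
              x$sampling_rate, x$t_zero_index))
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

#' Time axis in seconds relative to behavior onset
#'
#' Negative values denote time before the behavior, matching the convention
#' used for earliest-decoding-time reporting.
#'
#' @param x A [trial_set()].
#' @return Numeric vector of length `T` (seconds, `0` at `t_zero_index`).
#' @export
time_axis <- function(x) {
  stopifnot(inherits(x, "trial_set"))
  (seq_len(dim(x$data)[2L]) - x$t_zero_index) / x$sampling_rate
}

#' Subset a trial set by trial index
#'
#' @param x A [trial_set()].
#' @param i Trial indices.
#' @param ... Unused.
#' @return A [trial_set()] with the selected trials.
#' @export
`[.trial_set` <- function(x, i, ...) {
  trial_set(x$data[i, , , drop = FALSE], x$labels[i],
            sampling_rate = x$sampling_rate, t_zero_index = x$t_zero_index,
            channel_names = x$channel_names, meta = x$meta)
}
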