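#' Stratified K-fold cross-validation splits
#'
#' Partitions trials into `K` disjoint test folds covering every trial; within
#' each fold the remaining trials are split into a training and a validation
#' part at `validation_rate`, all splits stratified by label.  The validation
#' part monitors over-fitting during training; all reported metrics use the
#' test part.
#'
#' @param n_trials Number of trials (>= K).
#' @param labels Binary label per trial (used for stratification).
#' @param K Number of folds (default 5; must be >= 2).
#' @param validation_rate Fraction of the non-test trials held out for
#'   validation (default 0.2).
#' @param seed Optional RNG seed.
#' @return Object of class `cv_splits`: list with `folds` (each a list of
#'   `train`, `validation`, `test` index vectors), `K`, `validation_rate`.
#' @examples
#' sp <- make_cv_splits(100, rep(0:1, 50), seed = 1)
#' lengths(sp$folds[[1]])  # 64 train, 16 validation, 20 test
#' @export
make_cv_splits <- function(n_trials, labels, K = 5, validation_rate = 0.2,
                           seed = NULL) {
  if (K < 2L)
    stop("K must be >= 2: a single fold has no held-out structure",
         call. = FALSE)
  if (n_trials < K) stop("need at least K trials", call. = FALSE)
  stopifnot(length(labels) == n_trials, all(labels %in% c(0, 1)))
  if (!is.null(seed)) set.seed(seed)

  fold_of <- integer(n_trials)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_of[idx] <- rep_len(seq_len(K), length(idx))
  }

  folds <- lapply(seq_len(K), function(k) {
    test <- which(fold_of == k)
    rest <- which(fold_of != k)
    if (length(unique(labels[test])) < 2L)
      stop("stratification error: a class is absent from test fold ", k,
           call. = FALSE)
    val <- unlist(lapply(unique(labels), function(cl) {
      pool <- rest[labels[rest] == cl]
      sample(pool, round(validation_rate * length(pool)))
    }), use.names = FALSE)
    list(train = setdiff(rest, val), validation = sort(val), test = test)
  })

  structure(list(folds = folds, K = as.integer(K),
                 validation_rate = validation_rate, n_trials = n_trials),
            class = "cv_splits")
}

#' @export
print.cv_splits <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) lengths(f), integer(3))
  cat(sprintf("<cv_splits> %d folds over %d trials (validation rate %g)\n",
              x$K, x$n_trials, x$validation_rate))
  cat(sprintf("  fold sizes: train %s, validation %s, test %s\n",
              paste(sizes[1, ], collapse = "/"),
              paste(sizes[2, ], collapse = "/"),
              paste(sizes[3, ], collapse = "/")))
  invisible(x)
}
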