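# Causal transformer baseline: pre-LayerNorm encoder blocks with strictly
# causal self-attention (each position attends to itself and the past only)
# and a per-time-point sigmoid head, so y_t depends on inputs 1..t alone.
# Forward and backward passes are written out explicitly; gradients are
# verified against finite differences in the test suite.

LN_EPS <- 1e-5

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, g, cache) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

row_add <- function(X, b) X + matrix(b, nrow(X), length(b), byrow = TRUE)

tf_param_names <- function(n_layers) {
  per <- c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "g1", "be1", "g2", "be2", "W1", "b1", "W2", "b2")
  c("W_in", "b_in", "P", "gf", "bf", "w_out", "b_out",
    unlist(lapply(seq_len(n_layers), function(l) paste0("L", l, ".", per))))
}

#' Initialise causal-transformer parameters
#'
#' @param n_timepoints Sequence length `T` (the positional table is learned
#'   per position).
#' @param n_channels Input channels `R`.
#' @param n_layers Encoder blocks (default 2).
#' @param n_heads Attention heads (default 4; must divide `d_model`).
#' @param d_model Model width (default 64).
#' @param d_ff Feed-forward width (default `2 * d_model`).
#' @param seed Optional RNG seed.
#' @return Object of class `transformer_params` (flat named list of arrays
#'   plus a `config` attribute).
#' @export
causal_transformer_params <- function(n_timepoints, n_channels, n_layers = 2,
                                      n_heads = 4, d_model = 64,
                                      d_ff = 2 * d_model, seed = NULL) {
  if (d_model %% n_heads != 0)
    stop("d_model must be divisible by n_heads", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- d_model
  gl <- function(nr, nc) matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)),
                                nr, nc)
  p <- list(W_in = gl(d, n_channels), b_in = rep(0, d),
            P = matrix(rnorm(n_timepoints * d, sd = 0.02), n_timepoints, d),
            gf = rep(1, d), bf = rep(0, d),
            w_out = runif(d, -1, 1) * sqrt(6 / (d + 1)), b_out = 0)
  for (l in seq_len(n_layers)) {
    nm <- function(s) paste0("L", l, ".", s)
    p[[nm("Wq")]] <- gl(d, d); p[[nm("bq")]] <- rep(0, d)
    p[[nm("Wk")]] <- gl(d, d); p[[nm("bk")]] <- rep(0, d)
    p[[nm("Wv")]] <- gl(d, d); p[[nm("bv")]] <- rep(0, d)
    p[[nm("Wo")]] <- gl(d, d); p[[nm("bo")]] <- rep(0, d)
    p[[nm("g1")]] <- rep(1, d); p[[nm("be1")]] <- rep(0, d)
    p[[nm("g2")]] <- rep(1, d); p[[nm("be2")]] <- rep(0, d)
    p[[nm("W1")]] <- gl(d_ff, d); p[[nm("b1")]] <- rep(0, d_ff)
    p[[nm("W2")]] <- gl(d, d_ff); p[[nm("b2")]] <- rep(0, d)
  }
  structure(p, config = list(n_timepoints = n_timepoints,
                             n_channels = n_channels, n_layers = n_layers,
                             n_heads = n_heads, d_model = d, d_ff = d_ff),
            class = "transformer_params")
}

# Forward pass for one trial (X: T x R).  Returns y and, if cache, all the
# intermediates the backward pass needs.
tf_forward_trial <- function(p, X, cache = FALSE) {
  cf <- attr(p, "config")
  Tn <- nrow(X); d <- cf$d_model; H <- cf$n_heads; dk <- d %/% H
  scale <- 1 / sqrt(dk)
  mask <- upper.tri(matrix(0, Tn, Tn))          # j > i: future, masked
  E <- X %*% t(p$W_in) + matrix(p$b_in, Tn, d, byrow = TRUE) +
    p$P[seq_len(Tn), , drop = FALSE]
  C <- if (cache) list(X = X, layers = vector("list", cf$n_layers)) else NULL
  for (l in seq_len(cf$n_layers)) {
    nm <- function(s) p[[paste0("L", l, ".", s)]]
    ln1 <- layernorm_fwd(E, nm("g1"), nm("be1"))
    U <- ln1$y
    Q <- row_add(U %*% t(nm("Wq")), nm("bq"))
    K <- row_add(U %*% t(nm("Wk")), nm("bk"))
    V <- row_add(U %*% t(nm("Wv")), nm("bv"))
    O <- matrix(0, Tn, d)
    Ah <- vector("list", H)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale
      S[mask] <- -Inf
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      Ah[[h]] <- A
      O[, idx] <- A %*% V[, idx, drop = FALSE]
    }
    M <- row_add(O %*% t(nm("Wo")), nm("bo"))
    E1 <- E + M
    ln2 <- layernorm_fwd(E1, nm("g2"), nm("be2"))
    U2 <- ln2$y
    Z1 <- row_add(U2 %*% t(nm("W1")), nm("b1"))
    F1 <- pmax(Z1, 0)
    F2 <- row_add(F1 %*% t(nm("W2")), nm("b2"))
    E2 <- E1 + F2
    if (cache)
      C$layers[[l]] <- list(E = E, ln1 = ln1, U = U, Q = Q, K = K, V = V,
                            Ah = Ah, O = O, E1 = E1, ln2 = ln2, U2 = U2,
                            Z1 = Z1, F1 = F1)
    E <- E2
  }
  lnf <- layernorm_fwd(E, p$gf, p$bf)
  z <- drop(lnf$y %*% p$w_out) + p$b_out
  y <- 1 / (1 + exp(-z))
  if (cache) { C$Efin <- E; C$lnf <- lnf; C$y <- y }
  list(y = y, cache = C)
}

# Backward pass for one trial given the gradient dz with respect to the
# pre-sigmoid logits (length T).  Returns parameter gradients (flat list,
# same names as p) and the input gradient dX.
tf_backward_trial <- function(p, cache, dz) {
  cf <- attr(p, "config")
  Tn <- length(dz); d <- cf$d_model; H <- cf$n_heads; dk <- d %/% H
  scale <- 1 / sqrt(dk)
  g <- list()
  dUf <- outer(dz, p$w_out)
  g$w_out <- drop(crossprod(cache$lnf$y, dz))
  g$b_out <- sum(dz)
  lb <- layernorm_bwd(dUf, p$gf, cache$lnf)
  g$gf <- lb$dg; g$bf <- lb$db
  dE <- lb$dX
  for (l in rev(seq_len(cf$n_layers))) {
    cl <- cache$layers[[l]]
    nm <- function(s) p[[paste0("L", l, ".", s)]]
    gn <- function(s) paste0("L", l, ".", s)
    # feed-forward block
    dF2 <- dE
    g[[gn("W2")]] <- crossprod(dF2, cl$F1)
    g[[gn("b2")]] <- colSums(dF2)
    dF1 <- dF2 %*% nm("W2")
    dZ1 <- dF1 * (cl$Z1 > 0)
    g[[gn("W1")]] <- crossprod(dZ1, cl$U2)
    g[[gn("b1")]] <- colSums(dZ1)
    lb2 <- layernorm_bwd(dZ1 %*% nm("W1"), nm("g2"), cl$ln2)
    g[[gn("g2")]] <- lb2$dg; g[[gn("be2")]] <- lb2$db
    dE1 <- dE + lb2$dX
    # attention block
    dM <- dE1
    g[[gn("Wo")]] <- crossprod(dM, cl$O)
    g[[gn("bo")]] <- colSums(dM)
    dO <- dM %*% nm("Wo")
    dQ <- matrix(0, Tn, d); dK <- matrix(0, Tn, d); dV <- matrix(0, Tn, d)
    for (h in seq_len(H)) {
      idx <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cl$Ah[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, cl$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(A, dOh)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, idx] <- dS %*% cl$K[, idx, drop = FALSE] * scale
      dK[, idx] <- crossprod(dS, cl$Q[, idx, drop = FALSE]) * scale
    }
    g[[gn("Wq")]] <- crossprod(dQ, cl$U); g[[gn("bq")]] <- colSums(dQ)
    g[[gn("Wk")]] <- crossprod(dK, cl$U); g[[gn("bk")]] <- colSums(dK)
    g[[gn("Wv")]] <- crossprod(dV, cl$U); g[[gn("bv")]] <- colSums(dV)
    dU <- dQ %*% nm("Wq") + dK %*% nm("Wk") + dV %*% nm("Wv")
    lb1 <- layernorm_bwd(dU, nm("g1"), cl$ln1)
    g[[gn("g1")]] <- lb1$dg; g[[gn("be1")]] <- lb1$db
    dE <- dE1 + lb1$dX
  }
  g$P <- dE
  g$b_in <- colSums(dE)
  g$W_in <- crossprod(dE, cache$X)
  list(grads = g, dX = dE %*% p$W_in)
}

#' Forward pass of a causal transformer
#'
#' @param params A [causal_transformer_params()] bundle or a fitted
#'   [causal_transformer()] model.
#' @param x A [trial_set()] or `[trials x time x channels]` array.
#' @return An `output_trajectory` (see [rnn_forward()]); `y_t` depends only
#'   on inputs at times `1..t`.
#' @export
transformer_forward <- function(params, x) {
  if (inherits(params, "causal_transformer")) params <- params$weights
  stopifnot(inherits(params, "transformer_params"))
  X <- as_input_array(x)
  cf <- attr(params, "config")
  if (dim(X)[2L] > cf$n_timepoints)
    stop("trial length exceeds the positional table (T = ",
         cf$n_timepoints, ")", call. = FALSE)
  if (dim(X)[3L] != cf$n_channels)
    stop("channel dimension mismatch", call. = FALSE)
  n <- dim(X)[1L]; Tn <- dim(X)[2L]
  Y <- matrix(0, n, Tn)
  for (i in seq_len(n))
    Y[i, ] <- tf_forward_trial(params, matrix(X[i, , ], Tn, dim(X)[3L]))$y
  make_output_trajectory(list(y = Y), Tn)
}

#' Fit a causal transformer classifier
#'
#' The attention baseline: identical interface and loss strategies to
#' [tvrnn()], with strictly causal self-attention replacing recurrence.
#' Trained deterministically (no dropout) with Adam; the epoch of lowest
#' validation loss is checkpointed.
#'
#' @inheritParams tvrnn
#' @param n_layers,n_heads,d_model,d_ff Architecture, see
#'   [causal_transformer_params()].
#' @param strategy Loss placement: `"S2"` (all time points, default) or
#'   `"S1"` (final step only).
#' @return Object of class `causal_transformer` with `weights`
#'   (checkpointed), `final_weights`, `history`, `checkpoint_epoch`.
#'   Methods: `predict`, `print`, `coef`, `plot`.
#' @export
causal_transformer <- function(x, y = NULL, strategy = c("S2", "S1"),
                               n_layers = 2, n_heads = 4, d_model = 64,
                               d_ff = 2 * d_model, epochs = 200,
                               learning_rate = 1e-4, batch_size = 64,
                               validation = 0.2, seed = 1, verbose = FALSE) {
  strategy <- match.arg(strategy)
  X <- as_input_array(x)
  labels <- if (inherits(x, "trial_set")) x$labels else as.integer(y)
  if (is.null(labels)) stop("labels `y` are required", call. = FALSE)
  n <- dim(X)[1L]; Tn <- dim(X)[2L]; R <- dim(X)[3L]
  lw <- loss_weights_for(strategy, Tn)

  set.seed(seed)
  p <- causal_transformer_params(Tn, R, n_layers, n_heads, d_model, d_ff)

  if (is.null(validation) || identical(validation, 0)) {
    val_idx <- integer(0)
  } else if (length(validation) == 1L && validation > 0 && validation < 1) {
    val_idx <- sort(unlist(lapply(unique(labels), function(cl) {
      pool <- which(labels == cl)
      sample(pool, round(validation * length(pool)))
    }), use.names = FALSE))
  } else val_idx <- sort(as.integer(validation))
  train_idx <- setdiff(seq_len(n), val_idx)
  has_val <- length(val_idx) > 0L

  pn <- names(p)
  mst <- lapply(p, function(a) a * 0); vst <- mst
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8; step <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  best_val <- Inf; best_p <- p; best_epoch <- NA_integer_
  eval_set <- function(idx) {
    Y <- matrix(0, length(idx), Tn)
    for (j in seq_along(idx))
      Y[j, ] <- tf_forward_trial(p, matrix(X[idx[j], , ], Tn, R))$y
    Y
  }

  for (ep in seq_len(epochs)) {
    perm <- sample(train_idx)
    nb <- ceiling(length(perm) / batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      batch <- perm[((b - 1L) * batch_size + 1L):min(b * batch_size, length(perm))]
      acc <- lapply(p, function(a) a * 0)
      bl <- 0
      for (i in batch) {
        fw <- tf_forward_trial(p, matrix(X[i, , ], Tn, R), cache = TRUE)
        yl <- labels[i]
        bl <- bl + sum(lw * (-(yl * log(fw$y + 1e-12) +
                               (1 - yl) * log(1 - fw$y + 1e-12))))
        dz <- lw * (fw$y - yl) / length(batch)
        bw <- tf_backward_trial(p, fw$cache, dz)
        for (nmp in pn) acc[[nmp]] <- acc[[nmp]] + bw$grads[[nmp]]
      }
      bl <- bl / length(batch)
      if (!is.finite(bl))
        stop("transformer training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nmp in pn) {
        mst[[nmp]] <- b1 * mst[[nmp]] + (1 - b1) * acc[[nmp]]
        vst[[nmp]] <- b2 * vst[[nmp]] + (1 - b2) * acc[[nmp]]^2
        p[[nmp]] <- p[[nmp]] - learning_rate * corr * mst[[nmp]] /
          (sqrt(vst[[nmp]]) + aeps)
      }
      ep_loss <- ep_loss + bl * length(batch)
    }
    ep_loss <- ep_loss / length(perm)
    val_loss <- NA_real_; val_acc <- NA_real_
    if (has_val) {
      Yv <- eval_set(val_idx)
      val_loss <- if (strategy == "S1") loss_s1(Yv, labels[val_idx])
                  else loss_s2(Yv, labels[val_idx])
      val_acc <- mean(as.integer(Yv[, Tn] >= 0.5) == labels[val_idx])
      if (val_loss < best_val) { best_val <- val_loss; best_p <- p; best_epoch <- ep }
    }
    history[ep, ] <- list(ep, ep_loss, val_loss, val_acc)
    if (verbose && ep %% 20L == 0L)
      message(sprintf("epoch %d/%d: train %.4f val %.4f", ep, epochs,
                      ep_loss, val_loss))
  }
  if (!has_val || is.na(best_epoch)) { best_p <- p; best_epoch <- epochs }

  structure(list(weights = best_p, final_weights = p, strategy = strategy,
                 n_timepoints = Tn, n_channels = R, history = history,
                 checkpoint_epoch = best_epoch, best_val_loss = best_val,
                 seed = seed, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 train_index = train_idx, validation_index = val_idx,
                 call = match.call()),
            class = "causal_transformer")
}

#' @export
predict.causal_transformer <- function(object, newdata,
                                       type = c("prob", "class"),
                                       which = c("best", "final"), ...) {
  type <- match.arg(type); which <- match.arg(which)
  wt <- if (which == "best") object$weights else object$final_weights
  tr <- transformer_forward(wt, newdata)
  if (type == "prob") tr$y else tr$class_calls
}

#' @export
print.causal_transformer <- function(x, ...) {
  cf <- attr(x$weights, "config")
  cat(sprintf("<causal_transformer> %d layers x %d heads, width %d, T = %d, R = %d\n",
              cf$n_layers, cf$n_heads, cf$d_model, x$n_timepoints,
              x$n_channels))
  if (nrow(x$history))
    cat(sprintf("  %d epochs; checkpoint at epoch %d (val loss %.4f)\n",
                x$epochs, x$checkpoint_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
coef.causal_transformer <- function(object, ...) object$weights

#' @export
plot.causal_transformer <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "causal transformer training", ...)
  if (any(!is.na(h$val_loss))) lines(h$epoch, h$val_loss, lty = 2)
  invisible(x)
}
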