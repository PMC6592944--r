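# Small feed-forward network for binary classification: configurable ReLU
# hidden layers, sigmoid output, binary cross-entropy loss with L2 weight
# decay, trained full-batch with Adam. Written in plain matrix algebra —
# inputs here are small (tens of positional features, a few hundred
# observations), so full-batch training is both fast and deterministic.

#' Train a multilayer perceptron
#'
#' @param x Numeric feature matrix (n x p), already scaled by the caller.
#' @param y Binary response (0/1).
#' @param hidden Hidden layer sizes; the default 50-50-100 ReLU stack with a
#'   sigmoid output is the structure used throughout the evaluation harness.
#' @param l2 L2 penalty on weights (not biases).
#' @param lr Adam learning rate.
#' @param epochs Passes over the data.
#' @param batch_size Minibatch size; `Inf` trains full-batch.
#' @param weights Optional per-observation loss weights (e.g. inverse class
#'   frequencies); rescaled to mean 1.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return Object of class `rwov_mlp`.
#' @export
mlp_train <- function(x, y, hidden = c(50L, 50L, 100L), l2 = 1e-4,
                      lr = 0.01, epochs = 300L, batch_size = 32L,
                      weights = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- .binary_labels(y, check_both = FALSE)
  stopifnot(nrow(x) == length(y))
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y), all(weights > 0))
  weights <- weights / mean(weights)
  sizes <- c(ncol(x), hidden, 1L)
  L <- length(sizes) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                          sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    n <- nrow(x)
    bs <- if (!is.finite(batch_size)) n else min(as.integer(batch_size), n)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0L
    for (ep in seq_len(epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      for (b0 in seq(1L, n, by = bs)) {
        sel <- ord[b0:min(b0 + bs - 1L, n)]
        xb <- x[sel, , drop = FALSE]; yb <- y[sel]; wb <- weights[sel]
        # forward
        A <- vector("list", L + 1L)
        A[[1]] <- xb
        for (l in seq_len(L)) {
          z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], `+`)
          A[[l + 1L]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
        }
        p <- A[[L + 1L]]
        # backward; dZ for output layer of BCE + sigmoid
        dZ <- wb * (p - yb) / length(sel)
        gW <- vector("list", L); gb <- vector("list", L)
        for (l in L:1) {
          gW[[l]] <- crossprod(A[[l]], dZ) + l2 * W[[l]]
          gb[[l]] <- colSums(dZ)
          if (l > 1L) dZ <- (dZ %*% t(W[[l]])) * (A[[l]] > 0)
        }
        # Adam update
        t <- t + 1L
        for (l in seq_len(L)) {
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
          mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
          mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
          W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
          b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
        }
      }
    }
    structure(list(W = W, b = b, hidden = hidden), class = "rwov_mlp")
  })
}

#' Predict class-1 probabilities from a trained MLP
#'
#' @param model An `rwov_mlp` from [mlp_train()].
#' @param x Feature matrix on the same scale as training.
#' @return Numeric vector of sigmoid outputs in `(0, 1)`.
#' @export
mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "rwov_mlp"))
  a <- as.matrix(x)
  L <- length(model$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], `+`)
    a <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.numeric(a)
}
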