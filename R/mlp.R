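# Minimal single-hidden-layer ReLU multilayer perceptron for binary
# classification, trained by full-batch Adam on the cross-entropy loss.
# Fixed epoch budget, no early stopping, so results are fully determined
# by the RNG state at fit time.

mlp_fit <- function(X, y01, hidden = 16L, epochs = 500L, lr = 0.01) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  # He initialization for the ReLU layer, small normal for the head
  W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden, 0, 0.1), hidden, 1)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(pars, function(z) z * 0)
  v <- lapply(pars, function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (it in seq_len(epochs)) {
    H <- sweep(X %*% pars$W1, 2, pars$b1, `+`)
    A <- pmax(H, 0)
    z <- drop(A %*% pars$W2) + pars$b2
    prob <- 1 / (1 + exp(-z))
    dz <- (prob - y01) / n
    g <- list(
      W1 = crossprod(X, (matrix(dz, n, 1) %*% t(pars$W2)) * (H > 0)),
      b1 = colSums((matrix(dz, n, 1) %*% t(pars$W2)) * (H > 0)),
      W2 = crossprod(A, matrix(dz, n, 1)),
      b2 = sum(dz)
    )
    for (k in names(pars)) {
      m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
      v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
      mhat <- m[[k]] / (1 - beta1^it)
      vhat <- v[[k]] / (1 - beta2^it)
      pars[[k]] <- pars[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(pars = pars), class = "gdeeg_mlp")
}

mlp_predict_prob <- function(fit, X) {
  X <- matrix(X, ncol = nrow(fit$pars$W1))
  A <- pmax(sweep(X %*% fit$pars$W1, 2, fit$pars$b1, `+`), 0)
  z <- drop(A %*% fit$pars$W2) + fit$pars$b2
  1 / (1 + exp(-z))
}
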