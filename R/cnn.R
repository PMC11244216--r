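# Minimal 1-D convolutional network for the tabular risk study:
# conv (kernel 3, `filters` channels) over the ordered feature vector,
# ReLU, dense sigmoid head. Trained full-batch with Adam on the
# cross-entropy loss; weights are seeded so fits are reproducible.

cnn_fit <- function(x, y, filters = 16, kernel = 3, epochs = 200,
                    lr = 0.01, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x); n <- nrow(x)
  if (p < kernel) stopf("need at least %d features for kernel %d", kernel, kernel)
  npos <- p - kernel + 1L
  with_seed(seed, {
    W <- matrix(rnorm(kernel * filters, 0, sqrt(2 / kernel)), kernel, filters)
    b <- numeric(filters)
    v <- rnorm(npos * filters, 0, sqrt(2 / (npos * filters)))
    c0 <- 0
    pars <- list(W = W, b = b, v = v, c0 = c0)
    mom1 <- lapply(pars, function(p) p * 0)
    mom2 <- mom1
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

    forward <- function(pars) {
      Z <- matrix(0, n, npos * filters)
      for (pos in seq_len(npos)) {
        cols <- ((pos - 1L) * filters + 1L):(pos * filters)
        Z[, cols] <- x[, pos:(pos + kernel - 1L), drop = FALSE] %*% pars$W
        Z[, cols] <- sweep(Z[, cols, drop = FALSE], 2, pars$b, "+")
      }
      A <- pmax(Z, 0)
      phat <- plogis(as.numeric(A %*% pars$v) + pars$c0)
      list(Z = Z, A = A, phat = phat)
    }

    for (ep in seq_len(epochs)) {
      fw <- forward(pars)
      d <- (fw$phat - y) / n
      grads <- list(W = matrix(0, kernel, filters), b = numeric(filters),
                    v = as.numeric(t(fw$A) %*% d), c0 = sum(d))
      dA <- outer(d, pars$v)
      dZ <- dA * (fw$Z > 0)
      for (pos in seq_len(npos)) {
        cols <- ((pos - 1L) * filters + 1L):(pos * filters)
        dZp <- dZ[, cols, drop = FALSE]
        grads$W <- grads$W + t(x[, pos:(pos + kernel - 1L), drop = FALSE]) %*% dZp
        grads$b <- grads$b + colSums(dZp)
      }
      for (nm in names(pars)) {
        mom1[[nm]] <- beta1 * mom1[[nm]] + (1 - beta1) * grads[[nm]]
        mom2[[nm]] <- beta2 * mom2[[nm]] + (1 - beta2) * grads[[nm]]^2
        m_hat <- mom1[[nm]] / (1 - beta1^ep)
        v_hat <- mom2[[nm]] / (1 - beta2^ep)
        pars[[nm]] <- pars[[nm]] - lr * m_hat / (sqrt(v_hat) + eps)
      }
    }
    structure(list(pars = pars, kernel = kernel, filters = filters, p = p),
              class = "ecg_cnn")
  })
}

#' @export
predict.ecg_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != object$p) stopf("newdata has the wrong number of features")
  k <- object$kernel; filters <- object$filters
  npos <- object$p - k + 1L
  pars <- object$pars
  A <- matrix(0, nrow(x), npos * filters)
  for (pos in seq_len(npos)) {
    cols <- ((pos - 1L) * filters + 1L):(pos * filters)
    z <- x[, pos:(pos + k - 1L), drop = FALSE] %*% pars$W
    A[, cols] <- pmax(sweep(z, 2, pars$b, "+"), 0)
  }
  p <- plogis(as.numeric(A %*% pars$v) + pars$c0)
  if (type == "prob") p else as.integer(p > 0.5)
}
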