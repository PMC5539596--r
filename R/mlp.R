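# Internal feedforward network (logistic-sigmoid hidden layers, identity
# output) with analytic backpropagation gradients, trained by quasi-Newton
# L-BFGS-B on the mean squared error. Small dense problems only: parameter
# vectors of a few thousand entries, sample counts in the hundreds.

mlp_sizes <- function(n_in, hidden_layers, neurons_per_layer, n_out) {
  c(n_in, rep(neurons_per_layer, hidden_layers), n_out)
}

mlp_n_par <- function(sizes) {
  L <- length(sizes) - 1L
  sum(vapply(seq_len(L), function(l) sizes[l] * sizes[l + 1L] + sizes[l + 1L],
             numeric(1)))
}

# uniform Glorot-style init; biases zero; draws from the current RNG stream
mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  par <- numeric(0)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    par <- c(par, stats::runif(sizes[l] * sizes[l + 1L], -r, r),
             rep(0, sizes[l + 1L]))
  }
  par
}

mlp_unpack <- function(par, sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  pos <- 0L
  for (l in seq_len(L)) {
    nw <- sizes[l] * sizes[l + 1L]
    W[[l]] <- matrix(par[pos + seq_len(nw)], sizes[l], sizes[l + 1L])
    pos <- pos + nw
    b[[l]] <- par[pos + seq_len(sizes[l + 1L])]
    pos <- pos + sizes[l + 1L]
  }
  list(W = W, b = b)
}

mlp_forward <- function(X, net) {
  L <- length(net$W)
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% net$W[[l]] + rep(net$b[[l]], each = nrow(A))
    A <- if (l < L) 1 / (1 + exp(-Z)) else Z
  }
  A
}

# returns list(loss, grad) for 0.5 * mean over samples of squared error
mlp_loss_grad <- function(par, sizes, X, Y) {
  net <- mlp_unpack(par, sizes)
  L <- length(net$W)
  n <- nrow(X)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]] + rep(net$b[[l]], each = n)
    acts[[l + 1L]] <- if (l < L) 1 / (1 + exp(-Z)) else Z
  }
  err <- acts[[L + 1L]] - Y
  loss <- 0.5 * sum(err^2) / n
  delta <- err / n
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      A <- acts[[l]]
      delta <- (delta %*% t(net$W[[l]])) * A * (1 - A)
    }
  }
  grad <- numeric(0)
  for (l in seq_len(L)) grad <- c(grad, as.numeric(gW[[l]]), gb[[l]])
  list(loss = loss, grad = grad)
}

# multi-start L-BFGS-B; RNG must be seeded by the caller
mlp_train <- function(X, Y, sizes, max_iterations, n_starts = 3L) {
  fn <- function(p) mlp_loss_grad(p, sizes, X, Y)$loss
  gr <- function(p) mlp_loss_grad(p, sizes, X, Y)$grad
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- mlp_init(sizes)
    fit <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iterations, factr = 10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(par = best$par, loss = best$value, sizes = sizes)
}
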