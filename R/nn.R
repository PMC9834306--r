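# Compact feed-forward network in base R matrix code: dense/ReLU layers,
# mean-squared-error loss, manual backpropagation and an Adam optimizer.
# Written natively so the package has no deep-learning framework dependency;
# the layer sizes involved (a few hundred units, desk-scale data) are well
# within reach of BLAS-backed matrix multiplication.

.mlp_init <- function(sizes) {
  # sizes: c(n_in, hidden..., n_out); He initialisation for ReLU layers
  n_layers <- length(sizes) - 1
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

.mlp_forward <- function(net, X, keep = FALSE) {
  # X: batch x n_in; ReLU on all layers but the last (linear output)
  n_layers <- length(net$W)
  A <- vector("list", n_layers + 1)
  A[[1]] <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < n_layers) pmax(Z, 0) else Z
  }
  if (keep) A else A[[n_layers + 1]]
}

.mlp_backward <- function(net, A, dY) {
  # dY: gradient of loss wrt the linear output; returns gradients per layer
  n_layers <- length(net$W)
  gW <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- dY
  for (l in rev(seq_len(n_layers))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

.adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), walk)
      list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
           v = purrr::map(out, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
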