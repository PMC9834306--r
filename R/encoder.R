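# Scaled-down attention-encoder forecaster: the secondary time-series
# surrogate. A single encoder block (multi-head self-attention, dropout,
# layer-norm with residual, then a two-stage 1x1 convolution stack) is
# pooled over time and mapped to the next descriptor vector. Implemented
# natively with manual backpropagation (verified against finite differences
# in the test suite) and trained with Adam. On desk-scale data this model is
# expected to trail the per-feature boosted ensemble, mirroring the relative
# ordering of the two approaches.

#' Attention-encoder forecaster specification
#'
#' @param n_heads Attention heads.
#' @param head_size Dimensionality per head.
#' @param dropout Dropout probability applied after attention and inside the
#'   feed-forward stack during training.
#' @param layernorm_epsilon Numerical floor inside layer normalization.
#' @param ff_conv_filters Channel counts of the two 1x1 convolutions (the
#'   first uses ReLU); the default `c(4, 1)` funnels each token to a scalar
#'   before pooling.
#' @param n_blocks Encoder blocks (1 supported; the funnel output head
#'   precludes stacking).
#' @param epochs,batch_size,lr Training-loop settings.
#' @return Object of class `encoder_spec`.
#' @export
encoder_spec <- function(n_heads = 12, head_size = 256, dropout = 0.25,
                         layernorm_epsilon = 1e-6, ff_conv_filters = c(4, 1),
                         n_blocks = 1, epochs = 30, batch_size = 32,
                         lr = 1e-3) {
  stopifnot(n_heads >= 1, head_size >= 1, dropout >= 0, dropout < 1,
            layernorm_epsilon > 0, length(ff_conv_filters) == 2,
            all(ff_conv_filters >= 1), epochs >= 1, batch_size >= 1, lr > 0)
  if (n_blocks != 1) abort("only n_blocks = 1 is supported")
  structure(list(n_heads = as.integer(n_heads),
                 head_size = as.integer(head_size), dropout = dropout,
                 eps = layernorm_epsilon,
                 ff = as.integer(ff_conv_filters), n_blocks = 1L,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr),
            class = "encoder_spec")
}

.enc_init <- function(spec, n_features) {
  H <- spec$n_heads
  dh <- spec$head_size
  n <- n_features
  proj <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
  }
  list(
    Wq = purrr::map(seq_len(H), ~ proj(n, dh)),
    Wk = purrr::map(seq_len(H), ~ proj(n, dh)),
    Wv = purrr::map(seq_len(H), ~ proj(n, dh)),
    Wo = proj(H * dh, n), bo = rep(0, n),
    g1 = rep(1, n), b1 = rep(0, n),
    g2 = rep(1, n), b2 = rep(0, n),
    Wc1 = proj(n, spec$ff[1]), bc1 = rep(0, spec$ff[1]),
    Wc2 = proj(spec$ff[1], spec$ff[2]), bc2 = rep(0, spec$ff[2]),
    Wd = proj(spec$ff[2], n), bd = rep(0, n))
}

.layernorm_fwd <- function(X, g, b, eps) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  sg <- sqrt(v + eps)
  xhat <- xc / sg
  list(y = sweep(xhat, 2, g, "*") + matrix(b, nrow(X), length(b),
                                           byrow = TRUE),
       xhat = xhat, sg = sg)
}

.layernorm_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2, g, "*")
  n <- ncol(xhat)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sg
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# forward pass for one window X (w x n); masks: NULL (inference) or list of
# dropout masks (training, inverted-dropout scaling already applied)
.enc_forward <- function(p, spec, X, masks = NULL) {
  H <- spec$n_heads
  dh <- spec$head_size
  w <- nrow(X)
  heads <- vector("list", H)
  for (h in seq_len(H)) {
    Q <- X %*% p$Wq[[h]]
    K <- X %*% p$Wk[[h]]
    V <- X %*% p$Wv[[h]]
    S <- tcrossprod(Q, K) / sqrt(dh)
    S <- S - apply(S, 1, max)           # row-stable softmax
    E <- exp(S)
    A <- E / rowSums(E)
    heads[[h]] <- list(Q = Q, K = K, V = V, A = A, O = A %*% V)
  }
  O <- do.call(cbind, purrr::map(heads, "O"))
  attn <- sweep(O %*% p$Wo, 2, p$bo, "+")
  attn_d <- if (is.null(masks)) attn else attn * masks$m1
  ln1 <- .layernorm_fwd(X + attn_d, p$g1, p$b1, spec$eps)
  ln2 <- .layernorm_fwd(ln1$y, p$g2, p$b2, spec$eps)
  Z1 <- sweep(ln2$y %*% p$Wc1, 2, p$bc1, "+")
  C1 <- pmax(Z1, 0)
  C1d <- if (is.null(masks)) C1 else C1 * masks$m2
  C2 <- sweep(C1d %*% p$Wc2, 2, p$bc2, "+")
  pool <- colMeans(C2)
  out <- as.vector(pool %*% p$Wd) + p$bd
  list(out = out, X = X, heads = heads, O = O, attn = attn, attn_d = attn_d,
       ln1 = ln1, ln2 = ln2, Z1 = Z1, C1 = C1, C1d = C1d, C2 = C2,
       pool = pool, w = w)
}

.enc_backward <- function(p, spec, cache, dout) {
  H <- spec$n_heads
  dh <- spec$head_size
  w <- cache$w
  g <- list()
  g$bd <- dout
  g$Wd <- outer(cache$pool, dout)
  dpool <- as.vector(p$Wd %*% dout)
  dC2 <- matrix(dpool / w, nrow = w, ncol = length(dpool), byrow = TRUE)
  g$bc2 <- colSums(dC2)
  g$Wc2 <- crossprod(cache$C1d, dC2)
  dC1d <- tcrossprod(dC2, p$Wc2)
  dC1 <- if (is.null(cache$masks)) dC1d else dC1d * cache$masks$m2
  dZ1 <- dC1 * (cache$Z1 > 0)
  g$bc1 <- colSums(dZ1)
  g$Wc1 <- crossprod(cache$ln2$y, dZ1)
  dln2y <- tcrossprod(dZ1, p$Wc1)
  b2w <- .layernorm_bwd(cache$ln2, p$g2, dln2y)
  g$g2 <- b2w$dg
  g$b2 <- b2w$db
  b1w <- .layernorm_bwd(cache$ln1, p$g1, b2w$dX)
  g$g1 <- b1w$dg
  g$b1 <- b1w$db
  dres <- b1w$dX                         # grad wrt X + attn_d
  dattn <- if (is.null(cache$masks)) dres else dres * cache$masks$m1
  g$bo <- colSums(dattn)
  g$Wo <- crossprod(cache$O, dattn)
  dO <- tcrossprod(dattn, p$Wo)
  dX <- dres                             # residual path
  g$Wq <- vector("list", H)
  g$Wk <- vector("list", H)
  g$Wv <- vector("list", H)
  for (h in seq_len(H)) {
    hd <- cache$heads[[h]]
    dOh <- dO[, ((h - 1) * dh + 1):(h * dh), drop = FALSE]
    dA <- tcrossprod(dOh, hd$V)
    dV <- crossprod(hd$A, dOh)
    dS <- hd$A * (dA - rowSums(dA * hd$A))
    dS <- dS / sqrt(dh)
    dQ <- dS %*% hd$K
    dK <- crossprod(dS, hd$Q)
    g$Wq[[h]] <- crossprod(cache$X, dQ)
    g$Wk[[h]] <- crossprod(cache$X, dK)
    g$Wv[[h]] <- crossprod(cache$X, dV)
    dX <- dX + tcrossprod(dQ, p$Wq[[h]]) + tcrossprod(dK, p$Wk[[h]]) +
      tcrossprod(dV, p$Wv[[h]])
  }
  g[names(p)]
}

#' Train the attention-encoder forecaster
#'
#' Trains all encoder parameters end-to-end with Adam on mean-squared error
#' over next-step descriptor vectors. Deterministic given the seed.
#'
#' @param samples A [build_window_dataset()] result.
#' @param spec An [encoder_spec()].
#' @param seed RNG seed (initialisation, shuffling, dropout).
#' @return Object of class `encoder_forecaster` with the trained parameters,
#'   the per-epoch loss trace, and the window size; responds to
#'   [predict_next()].
#' @export
train_encoder_forecaster <- function(samples, spec = encoder_spec(),
                                     seed = 1L) {
  stopifnot(inherits(samples, "window_dataset"), nrow(samples) > 0)
  w_s <- attr(samples, "w_s")
  n_features <- length(samples$target[[1]])
  withr::local_seed(seed)
  params <- .enc_init(spec, n_features)
  opt <- .adam_init(params)
  n <- nrow(samples)
  loss_trace <- numeric(spec$epochs)

  scale_mask <- function(dim1, dim2) {
    if (spec$dropout == 0) return(matrix(1, dim1, dim2))
    (matrix(runif(dim1 * dim2), dim1, dim2) >= spec$dropout) /
      (1 - spec$dropout)
  }

  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      grads <- NULL
      for (i in idx) {
        X <- samples$window[[i]]
        y <- samples$target[[i]]
        masks <- list(m1 = scale_mask(w_s, n_features),
                      m2 = scale_mask(w_s, spec$ff[1]))
        cache <- .enc_forward(params, spec, X, masks)
        cache$masks <- masks
        err <- cache$out - y
        ep_loss <- ep_loss + sum(err^2) / n_features
        gi <- .enc_backward(params, spec, cache, 2 * err / n_features)
        grads <- if (is.null(grads)) gi else .nested_add(grads, gi)
      }
      grads <- .nested_scale(grads, 1 / length(idx))
      step <- .adam_step(params, grads, opt, lr = spec$lr)
      params <- step$params
      opt <- step$state
    }
    loss_trace[epoch] <- ep_loss / n
  }
  structure(list(params = params, spec = spec, w_s = w_s,
                 n_features = n_features, seed = as.integer(seed),
                 loss_trace = loss_trace),
            class = "encoder_forecaster")
}

.nested_add <- function(a, b) {
  if (is.list(a)) purrr::map2(a, b, .nested_add) else a + b
}

.nested_scale <- function(a, s) {
  if (is.list(a)) purrr::map(a, .nested_scale, s = s) else a * s
}

#' @export
predict_next.encoder_forecaster <- function(bundle, window) {
  window <- as.matrix(window)
  if (nrow(window) != bundle$w_s || ncol(window) != bundle$n_features) {
    abort(paste0("window must be ", bundle$w_s, " x ", bundle$n_features,
                 ", got ", nrow(window), " x ", ncol(window)))
  }
  .enc_forward(bundle$params, bundle$spec, window)$out
}

#' @export
print.encoder_forecaster <- function(x, ...) {
  cat("<encoder_forecaster> ", x$spec$n_heads, " heads x ", x$spec$head_size,
      ", w_s = ", x$w_s, ", final loss ",
      format(tail(x$loss_trace, 1), digits = 4), "\n", sep = "")
  invisible(x)
}
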