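# SASA regression: map one descriptor vector to a SASA value. The primary
# model is a feed-forward network (4 x 256 ReLU layers, linear output unit,
# Adam); a gradient-boosted regressor is available behind the same interface
# as a shallow baseline. Targets are z-scored internally during training and
# predictions are mapped back to Angstrom^2, so the optimizer works on a
# unit-scale problem regardless of the absolute SASA magnitude.

#' Feed-forward SASA network specification
#'
#' @param hidden Hidden layer widths (ReLU); default four layers of 256.
#' @param epochs Passes over the training set.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param standardize_inputs If `TRUE`, z-score the descriptor features
#'   before training (off by default; the trees of the baseline are
#'   scale-invariant and the raw descriptor scale is informative).
#' @return Object of class `sasa_net_spec`.
#' @export
sasa_net_spec <- function(hidden = c(256, 256, 256, 256), epochs = 500,
                          batch_size = 32, lr = 1e-4,
                          standardize_inputs = FALSE) {
  stopifnot(all(hidden > 0), epochs > 0, batch_size > 0, lr > 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 standardize_inputs = isTRUE(standardize_inputs)),
            class = "sasa_net_spec")
}

#' Gradient-boosted SASA baseline specification
#'
#' Same training interface as [sasa_net_spec()], backed by boosted trees.
#'
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @return Object of class `sasa_gbm_spec`.
#' @export
sasa_gbm_spec <- function(nrounds = 200, max_depth = 6, eta = 0.1) {
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta),
            class = "sasa_gbm_spec")
}

# align a descriptor table with a SASA series into X / y
.sasa_xy <- function(mbtr_table, sasa_series) {
  joined <- dplyr::inner_join(mbtr_table, sasa_series,
                              by = c("design_id", "timestep"))
  if (nrow(joined) != nrow(mbtr_table)) {
    abort("descriptor table and SASA series do not align on (design_id, timestep)")
  }
  list(X = .feature_matrix(joined), y = joined$sasa)
}

#' Train a SASA regressor on descriptor rows
#'
#' Each row of the descriptor table is paired with the design's SASA at the
#' same timestep. Training is deterministic given the seed.
#'
#' @param mbtr_table Descriptor tibble (`design_id`, `timestep`, `f*`).
#' @param sasa_series Tibble `design_id`, `timestep`, `sasa`.
#' @param spec A [sasa_net_spec()] or [sasa_gbm_spec()].
#' @param seed RNG seed.
#' @return Fitted model of class `sasa_net` or `sasa_gbm`; both respond to
#'   [predict_sasa()].
#' @export
train_sasa_model <- function(mbtr_table, sasa_series, spec = sasa_net_spec(),
                             seed = 1L) {
  UseMethod("train_sasa_model", spec)
}

#' @export
train_sasa_model.default <- function(mbtr_table, sasa_series, spec, seed) {
  abort("spec must be a sasa_net_spec or sasa_gbm_spec")
}

#' @export
train_sasa_model.sasa_net_spec <- function(mbtr_table, sasa_series,
                                           spec = sasa_net_spec(),
                                           seed = 1L) {
  dat <- .sasa_xy(mbtr_table, sasa_series)
  X <- dat$X
  y <- dat$y
  n <- nrow(X)
  withr::local_seed(seed)

  x_center <- rep(0, ncol(X))
  x_scale <- rep(1, ncol(X))
  if (spec$standardize_inputs) {
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, sd)
    x_scale[x_scale < 1e-12] <- 1
    X <- scale(X, center = x_center, scale = x_scale)
  }
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  net <- .mlp_init(c(ncol(X), spec$hidden, 1L))
  params <- list(W = net$W, b = net$b)
  opt <- .adam_init(params)
  loss_trace <- numeric(spec$epochs)

  for (epoch in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      net$W <- params$W
      net$b <- params$b
      A <- .mlp_forward(net, X[idx, , drop = FALSE], keep = TRUE)
      pred <- A[[length(A)]]
      err <- pred - ys[idx]
      ep_loss <- ep_loss + sum(err^2)
      dY <- 2 * err / length(idx)
      grads <- .mlp_backward(net, A, dY)
      step <- .adam_step(params, grads, opt, lr = spec$lr)
      params <- step$params
      opt <- step$state
    }
    loss_trace[epoch] <- ep_loss / n
  }
  net$W <- params$W
  net$b <- params$b

  structure(list(net = net, spec = spec, seed = as.integer(seed),
                 n_features = ncol(X), x_center = x_center,
                 x_scale = x_scale, y_center = y_center, y_scale = y_scale,
                 loss_trace = loss_trace),
            class = "sasa_net")
}

#' @export
train_sasa_model.sasa_gbm_spec <- function(mbtr_table, sasa_series,
                                           spec = sasa_gbm_spec(),
                                           seed = 1L) {
  dat <- .sasa_xy(mbtr_table, sasa_series)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = spec$max_depth,
                  eta = spec$eta, nthread = 1, seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(dat$X, label = dat$y),
    nrounds = spec$nrounds, verbose = 0)
  structure(list(booster = booster, spec = spec, seed = as.integer(seed),
                 n_features = ncol(dat$X)),
            class = "sasa_gbm")
}

#' Predict SASA from descriptor vectors
#'
#' @param model A fitted `sasa_net` or `sasa_gbm`.
#' @param v A length-`n_features` vector, or a matrix / descriptor tibble of
#'   rows to predict.
#' @return Numeric vector of SASA predictions (Angstrom^2).
#' @export
predict_sasa <- function(model, v) {
  UseMethod("predict_sasa")
}

.as_pred_matrix <- function(model, v) {
  m <- if (is.data.frame(v)) .feature_matrix(v)
       else if (is.matrix(v)) v
       else matrix(v, nrow = 1)
  if (ncol(m) != model$n_features) {
    abort(paste0("expected ", model$n_features, " features, got ", ncol(m)))
  }
  m
}

#' @export
predict_sasa.sasa_net <- function(model, v) {
  m <- .as_pred_matrix(model, v)
  m <- sweep(sweep(m, 2, model$x_center, "-"), 2, model$x_scale, "/")
  out <- .mlp_forward(model$net, m)
  as.vector(out) * model$y_scale + model$y_center
}

#' @export
predict_sasa.sasa_gbm <- function(model, v) {
  m <- .as_pred_matrix(model, v)
  predict(model$booster, xgboost::xgb.DMatrix(m))
}

#' @export
print.sasa_net <- function(x, ...) {
  cat("<sasa_net> layers ", paste(x$net$sizes, collapse = "-"),
      ", final training loss ", format(tail(x$loss_trace, 1), digits = 4),
      " (z-scored)\n", sep = "")
  invisible(x)
}

#' @export
print.sasa_gbm <- function(x, ...) {
  cat("<sasa_gbm> ", x$spec$nrounds, " trees, depth ", x$spec$max_depth,
      "\n", sep = "")
  invisible(x)
}

#' Held-out MAE of a SASA model
#'
#' @param model Fitted SASA model.
#' @param mbtr_table,sasa_series Held-out descriptor rows and matching SASA.
#' @return Scalar MAE in Angstrom^2.
#' @export
sasa_model_mae <- function(model, mbtr_table, sasa_series) {
  dat <- .sasa_xy(mbtr_table, sasa_series)
  mae(predict_sasa(model, dat$X), dat$y)
}
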