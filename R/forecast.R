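# Sliding-window forecasting of the descriptor trajectory. The primary
# surrogate is an ensemble of one gradient-boosted regressor per descriptor
# feature: model f sees only the last w_s values of feature f and predicts
# its next value; the per-feature predictions are concatenated into the next
# descriptor vector.

#' Build a sliding-window dataset from descriptor tables
#'
#' For every design of length `T`, emits exactly `T - w_s` samples: windows
#' of `w_s` consecutive descriptor vectors with the following vector as the
#' target. Samples never cross design boundaries, and every window timestep
#' strictly precedes its target (asserted on construction).
#'
#' @param mbtr_table Descriptor tibble (`design_id`, `timestep`, `f*`).
#' @param w_s Window size (timesteps).
#' @return Tibble of class `window_dataset`: `design_id`, `target_timestep`,
#'   `window` (list of `w_s x n_features` matrices), `target` (list of
#'   length-`n_features` vectors).
#' @export
build_window_dataset <- function(mbtr_table, w_s) {
  stopifnot(w_s >= 1)
  feats <- grep("^f[0-9]+$", names(mbtr_table), value = TRUE)
  out <- mbtr_table |>
    dplyr::arrange(.data$design_id, .data$timestep) |>
    dplyr::group_by(.data$design_id) |>
    dplyr::group_map(function(d, key) {
      T_d <- nrow(d)
      if (T_d <= w_s) {
        abort(paste0("design ", key$design_id, " has length ", T_d,
                     " <= window size ", w_s))
      }
      m <- as.matrix(d[, feats])
      ts <- d$timestep
      purrr::map(seq(w_s + 1L, T_d), function(i) {
        if (!all(ts[(i - w_s):(i - 1)] < ts[i])) {
          abort("window timesteps do not precede the target")  # leakage guard
        }
        list(design_id = key$design_id, target_timestep = ts[i],
             window = m[(i - w_s):(i - 1), , drop = FALSE],
             target = m[i, ])
      })
    })
  out <- purrr::flatten(out)
  structure(tibble::tibble(
    design_id = purrr::map_chr(out, "design_id"),
    target_timestep = purrr::map_int(out, ~ as.integer(.x$target_timestep)),
    window = purrr::map(out, "window"),
    target = purrr::map(out, "target")),
    class = c("window_dataset", "tbl_df", "tbl", "data.frame"),
    w_s = as.integer(w_s))
}

#' @export
`[.window_dataset` <- function(x, ...) {
  out <- NextMethod()
  attr(out, "w_s") <- attr(x, "w_s")
  class(out) <- class(x)
  out
}

#' Ensemble hyperparameters
#'
#' Gradient-boosting settings shared by all per-feature models.
#'
#' @param nrounds Number of trees.
#' @param max_depth Maximum tree depth.
#' @param eta Learning rate.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(nrounds = 100, max_depth = 6, eta = 0.3) {
  stopifnot(nrounds >= 1, max_depth >= 1, eta > 0)
  structure(list(nrounds = as.integer(nrounds),
                 max_depth = as.integer(max_depth), eta = eta),
            class = "ensemble_spec")
}

# samples x w_s lag matrix of one feature, plus its targets
.feature_lags <- function(samples, f) {
  w_s <- attr(samples, "w_s")
  X <- t(vapply(samples$window, function(W) W[, f], numeric(w_s)))
  y <- vapply(samples$target, function(v) v[f], numeric(1))
  list(X = X, y = y)
}

#' Train the per-feature gradient-boosted ensemble
#'
#' Fits one univariate boosted-tree regressor per descriptor feature; model
#' f is trained on the `w_s` past values of feature f only. Training is
#' single-threaded with a fixed seed, so the bundle is deterministic.
#'
#' @param samples A [build_window_dataset()] result.
#' @param hyper An [ensemble_spec()].
#' @param seed RNG seed for the boosters.
#' @param eval_samples Optional held-out `window_dataset` on which the
#'   per-feature MAE report is computed (training samples are used when
#'   absent).
#' @return Object of class `mbtr_forecaster`: `w_s`, `n_features`, `models`,
#'   `hyper`, `seed`, and `report` (tibble `feature`, `mae`).
#' @export
train_ensemble <- function(samples, hyper = ensemble_spec(), seed = 1L,
                           eval_samples = NULL) {
  stopifnot(inherits(samples, "window_dataset"), nrow(samples) > 0)
  w_s <- attr(samples, "w_s")
  n_features <- length(samples$target[[1]])
  models <- vector("list", n_features)
  for (f in seq_len(n_features)) {
    lag <- .feature_lags(samples, f)
    dtrain <- xgboost::xgb.DMatrix(lag$X, label = lag$y)
    models[[f]] <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = hyper$max_depth, eta = hyper$eta,
                    nthread = 1, seed = as.integer(seed)),
      data = dtrain, nrounds = hyper$nrounds, verbose = 0)
  }
  bundle <- structure(list(w_s = w_s, n_features = n_features,
                           models = models, hyper = hyper,
                           seed = as.integer(seed), report = NULL),
                      class = "mbtr_forecaster")
  rep_on <- if (is.null(eval_samples)) samples else eval_samples
  bundle$report <- .ensemble_report(bundle, rep_on)
  bundle
}

.ensemble_report <- function(bundle, samples) {
  per_feature <- vapply(seq_len(bundle$n_features), function(f) {
    lag <- .feature_lags(samples, f)
    pred <- predict(bundle$models[[f]], xgboost::xgb.DMatrix(lag$X))
    mean(abs(pred - lag$y))
  }, numeric(1))
  tibble::tibble(feature = paste0("f", seq_len(bundle$n_features) - 1L),
                 mae = per_feature)
}

#' @export
print.mbtr_forecaster <- function(x, ...) {
  cat("<mbtr_forecaster> ", x$n_features, " per-feature boosted models, w_s = ",
      x$w_s, ", mean MAE ", format(mean(x$report$mae), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' One-step prediction of the next descriptor vector
#'
#' Applies each per-feature model to its own feature column of the window
#' and concatenates the outputs in feature order.
#'
#' @param bundle An [train_ensemble()] bundle (or encoder forecaster).
#' @param window `w_s x n_features` numeric matrix of consecutive descriptor
#'   vectors.
#' @return Numeric vector of length `n_features`.
#' @export
predict_next <- function(bundle, window) {
  UseMethod("predict_next")
}

#' @export
predict_next.mbtr_forecaster <- function(bundle, window) {
  window <- as.matrix(window)
  if (nrow(window) != bundle$w_s || ncol(window) != bundle$n_features) {
    abort(paste0("window must be ", bundle$w_s, " x ", bundle$n_features,
                 ", got ", nrow(window), " x ", ncol(window)))
  }
  vapply(seq_len(bundle$n_features), function(f) {
    predict(bundle$models[[f]],
            xgboost::xgb.DMatrix(matrix(window[, f], nrow = 1)))
  }, numeric(1))
}

#' Mean absolute error
#'
#' Mean over all entries of the absolute element-wise differences.
#'
#' @param predicted,actual Numeric vectors or matrices of identical shape.
#' @return Scalar MAE.
#' @export
mae <- function(predicted, actual) {
  if (!identical(dim(predicted), dim(actual)) ||
      length(predicted) != length(actual)) {
    abort("predicted and actual differ in shape")
  }
  mean(abs(predicted - actual))
}

#' One-step test MAE of a forecaster over a window dataset
#'
#' @param bundle Forecaster.
#' @param samples `window_dataset`.
#' @return Scalar MAE over all samples and features.
#' @export
one_step_mae <- function(bundle, samples) {
  if (inherits(bundle, "mbtr_forecaster")) {
    # batched per feature: equal sample counts, so the grand MAE is the mean
    # of per-feature MAEs
    return(mean(.ensemble_report(bundle, samples)$mae))
  }
  preds <- t(vapply(samples$window, function(W) predict_next(bundle, W),
                    numeric(bundle$n_features)))
  actual <- do.call(rbind, samples$target)
  mae(preds, actual)
}
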