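# Combined inference: iterated one-step forecasting of the descriptor
# trajectory from a seed window (rollout), followed by SASA regression on
# the state reached at the target timestep.
#
# Timestep convention: snapshots carry 0-based indices 0..T-1; the target t
# is the 1-based ordinal of the target snapshot (t = T reaches the final
# state of a T-step trajectory). A seed window covers indices 0..w_s-1 and
# a rollout to t forecasts indices w_s..t-1: exactly t - w_s steps, the
# last of which is the t-th snapshot. This keeps "260 steps ahead" at
# w_s = 40, t = 300 on a 300-step design.

#' Roll a forecaster forward to a target timestep
#'
#' Starting from the seed window (snapshot indices `0 .. w_s-1`), predicts
#' the next descriptor vector, appends it, slides the window by one, and
#' repeats until the `t`-th snapshot is produced — `t - w_s` steps in total.
#' `t` is the 1-based ordinal of the target snapshot, so `t = T` reaches
#' the final state of a `T`-step trajectory (0-based index `t - 1`).
#'
#' @param bundle A trained forecaster ([train_ensemble()] or
#'   [train_encoder_forecaster()]).
#' @param seed_window `w_s x n_features` matrix of observed descriptor
#'   vectors.
#' @param t Target snapshot ordinal, > `w_s`.
#' @param design_id Optional label carried into the result.
#' @return Object of class `rollout_result`: `design_id`, `t`, `n_steps`,
#'   and `predicted` — a tibble of the forecast vectors with 0-based
#'   `timestep` indices `w_s .. t-1` (feature columns `f*`).
#' @export
rollout <- function(bundle, seed_window, t, design_id = NA_character_) {
  w_s <- bundle$w_s
  if (t <= w_s) {
    abort(paste0("target timestep t = ", t, " must exceed the window size ",
                 w_s))
  }
  seed_window <- as.matrix(seed_window)
  stopifnot(nrow(seed_window) == w_s)
  n_steps <- as.integer(t - w_s)
  preds <- matrix(NA_real_, nrow = n_steps, ncol = bundle$n_features)
  window <- seed_window
  for (k in seq_len(n_steps)) {
    nxt <- predict_next(bundle, window)
    preds[k, ] <- nxt
    window <- rbind(window[-1, , drop = FALSE], nxt)
  }
  colnames(preds) <- paste0("f", seq_len(bundle$n_features) - 1L)
  predicted <- tibble::as_tibble(preds)
  predicted <- dplyr::mutate(predicted,
                             timestep = seq(w_s, as.integer(t) - 1L),
                             .before = 1)
  structure(list(design_id = design_id, t = as.integer(t),
                 w_s = as.integer(w_s), n_steps = n_steps,
                 predicted = predicted),
            class = "rollout_result")
}

#' @export
print.rollout_result <- function(x, ...) {
  cat("<rollout_result> ", x$n_steps, " forecast steps to t = ", x$t,
      " (w_s = ", x$w_s, ")\n", sep = "")
  invisible(x)
}

#' Combined surrogate inference of SASA at a target timestep
#'
#' Rolls the forecaster out to timestep `t` and applies the SASA regressor
#' to the final predicted descriptor vector.
#'
#' @inheritParams rollout
#' @param sasa_model Fitted SASA regressor (see [train_sasa_model()]).
#' @return Scalar predicted SASA (Angstrom^2).
#' @export
combined_inference <- function(bundle, sasa_model, seed_window, t) {
  ro <- rollout(bundle, seed_window, t)
  final <- as.numeric(ro$predicted[nrow(ro$predicted),
                                   grep("^f[0-9]+$", names(ro$predicted))])
  predict_sasa(sasa_model, final)
}

#' Mean absolute SASA error over test designs
#'
#' The end-point evaluation metric: the mean absolute deviation between
#' predicted and ground-truth SASA at the target timestep, averaged over the
#' `k` designs of a test set.
#'
#' @param predictions,truths Numeric vectors of equal length `k >= 1`.
#' @return Scalar mean absolute deviation (Angstrom^2).
#' @export
error_sasa <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) < 1) {
    abort("predictions and truths must have equal positive length")
  }
  mean(abs(predictions - truths))
}

#' Ratio of final to initial SASA, in percent
#'
#' `100 * sasa_t / sasa_0`; report tables round this to integer percent.
#'
#' @param sasa_t SASA at the target timestep.
#' @param sasa_0 Initial SASA, > 0.
#' @return Scalar percent.
#' @export
percent_change <- function(sasa_t, sasa_0) {
  if (any(sasa_0 <= 0)) abort("initial SASA must be positive")
  100 * sasa_t / sasa_0
}

#' Window-size sweep of the combined pipeline
#'
#' For each window size: builds train/test window datasets, trains the
#' per-feature ensemble (timing it), records the one-step test MAE, rolls
#' out each test design from its first `w_s` observed descriptor vectors to
#' timestep `t`, regresses SASA from the final state, and scores
#' [error_sasa()] against the oracle values. The SASA regressor is trained
#' once on the training designs and shared across window sizes.
#'
#' @param dataset An [make_dataset()] result (or compatible list with
#'   `trajectory`, `sasa`, `manifest`).
#' @param window_sizes Integer window sizes, all `< t`.
#' @param t Target timestep (0-based); defaults to the last common timestep.
#' @param cfg [mbtr_config()] used for encoding.
#' @param hyper [ensemble_spec()] for the forecasters.
#' @param sasa_spec [sasa_net_spec()] or [sasa_gbm_spec()] for the
#'   regressor.
#' @param seed RNG seed.
#' @param mbtr_table Optional precomputed descriptor table (skips encoding).
#' @return Tibble of class `window_sweep`, sorted by `w_s`, with columns
#'   `w_s`, `train_time_s`, `ensemble_mae`, `error_sasa` and logical minima
#'   marks `min_mae`, `min_error`; per-design predictions are attached as
#'   attribute `"designs"` (a Table-2-shaped tibble with integer-rounded
#'   percent changes).
#' @export
window_sweep <- function(dataset, window_sizes = c(10, 20, 40, 60, 80),
                         t = NULL, cfg = mbtr_config(),
                         hyper = ensemble_spec(),
                         sasa_spec = sasa_net_spec(), seed = 1L,
                         mbtr_table = NULL) {
  stopifnot(length(window_sizes) >= 1)
  manifest <- dataset$manifest
  if (is.null(t)) t <- min(manifest$T)
  if (any(window_sizes >= t)) {
    abort("all window sizes must be smaller than the target timestep")
  }
  if (is.null(mbtr_table)) {
    mbtr_table <- encode_trajectory(dataset$trajectory, cfg)
  }
  train_ids <- manifest$design_id[manifest$split == "train"]
  test_ids <- manifest$design_id[manifest$split == "test"]
  mbtr_train <- dplyr::filter(mbtr_table, .data$design_id %in% train_ids)
  mbtr_test <- dplyr::filter(mbtr_table, .data$design_id %in% test_ids)
  sasa_train <- dplyr::filter(dataset$sasa, .data$design_id %in% train_ids)

  sasa_model <- train_sasa_model(mbtr_train, sasa_train, sasa_spec,
                                 seed = seed)

  truth_at_t <- dataset$sasa |>
    dplyr::filter(.data$design_id %in% test_ids, .data$timestep == t - 1L)
  truth_at_0 <- dataset$sasa |>
    dplyr::filter(.data$design_id %in% test_ids, .data$timestep == 0)

  rows <- purrr::map(sort(window_sizes), function(w_s) {
    train_windows <- build_window_dataset(mbtr_train, w_s)
    test_windows <- build_window_dataset(mbtr_test, w_s)
    elapsed <- system.time(
      bundle <- train_ensemble(train_windows, hyper, seed = seed,
                               eval_samples = test_windows))["elapsed"]
    step_mae <- mean(bundle$report$mae)

    per_design <- purrr::map(test_ids, function(id) {
      rows_d <- dplyr::filter(mbtr_test, .data$design_id == id) |>
        dplyr::arrange(.data$timestep)
      seed_window <- .feature_matrix(rows_d)[seq_len(w_s), , drop = FALSE]
      pred <- combined_inference(bundle, sasa_model, seed_window, t)
      tibble::tibble(design_id = id, predicted_sasa = pred)
    }) |> dplyr::bind_rows()

    joined <- per_design |>
      dplyr::left_join(dplyr::select(truth_at_t, "design_id",
                                     actual_sasa = "sasa"),
                       by = "design_id") |>
      dplyr::left_join(dplyr::select(truth_at_0, "design_id",
                                     sasa0 = "sasa"), by = "design_id") |>
      dplyr::mutate(
        predicted_change_pct = round(percent_change(.data$predicted_sasa,
                                                    .data$sasa0)),
        actual_change_pct = round(percent_change(.data$actual_sasa,
                                                 .data$sasa0)),
        w_s = w_s) |>
      dplyr::select("w_s", "design_id", "predicted_sasa",
                    "predicted_change_pct", "actual_sasa",
                    "actual_change_pct")

    list(summary = tibble::tibble(
      w_s = as.integer(w_s), train_time_s = unname(elapsed),
      ensemble_mae = step_mae,
      error_sasa = error_sasa(joined$predicted_sasa, joined$actual_sasa)),
      designs = joined)
  })

  out <- dplyr::bind_rows(purrr::map(rows, "summary"))
  out$min_mae <- out$ensemble_mae == min(out$ensemble_mae)
  out$min_error <- out$error_sasa == min(out$error_sasa)
  structure(out, class = c("window_sweep", class(out)),
            designs = dplyr::bind_rows(purrr::map(rows, "designs")),
            t = as.integer(t))
}

#' Predict-the-mean SASA baseline error
#'
#' The error of always predicting the training designs' mean SASA at the
#' target timestep; a surrogate must beat this to demonstrate signal.
#'
#' @param dataset An [make_dataset()] result.
#' @param t Target snapshot ordinal (as in [rollout()]).
#' @return Scalar [error_sasa()] of the constant prediction on test designs.
#' @export
mean_baseline_error <- function(dataset, t) {
  manifest <- dataset$manifest
  train_mean <- dataset$sasa |>
    dplyr::filter(.data$design_id %in%
                    manifest$design_id[manifest$split == "train"],
                  .data$timestep == t - 1L)
  truths <- dataset$sasa |>
    dplyr::filter(.data$design_id %in%
                    manifest$design_id[manifest$split == "test"],
                  .data$timestep == t - 1L)
  error_sasa(rep(mean(train_mean$sasa), nrow(truths)), truths$sasa)
}
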