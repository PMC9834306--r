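# broom-style accessors for the fitted objects.

#' @export
tidy.mbtr_forecaster <- function(x, ...) {
  x$report
}

#' @export
glance.mbtr_forecaster <- function(x, ...) {
  tibble::tibble(w_s = x$w_s, n_features = x$n_features,
                 n_models = length(x$models),
                 mean_mae = mean(x$report$mae), seed = x$seed)
}

#' @export
tidy.sasa_net <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @export
glance.sasa_net <- function(x, ...) {
  tibble::tibble(layers = paste(x$net$sizes, collapse = "-"),
                 epochs = x$spec$epochs, lr = x$spec$lr,
                 final_loss = tail(x$loss_trace, 1), seed = x$seed)
}

#' @export
tidy.encoder_forecaster <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @export
glance.encoder_forecaster <- function(x, ...) {
  tibble::tibble(n_heads = x$spec$n_heads, head_size = x$spec$head_size,
                 w_s = x$w_s, n_features = x$n_features,
                 final_loss = tail(x$loss_trace, 1), seed = x$seed)
}

#' @export
tidy.shap_values <- function(x, ...) {
  tibble::as_tibble(x$values) |>
    dplyr::mutate(row = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"row", names_to = "feature",
                        values_to = "contribution")
}

#' @export
glance.window_sweep <- function(x, ...) {
  tibble::tibble(best_w_s_mae = x$w_s[which.min(x$ensemble_mae)],
                 best_w_s_error = x$w_s[which.min(x$error_sasa)],
                 min_ensemble_mae = min(x$ensemble_mae),
                 min_error_sasa = min(x$error_sasa))
}
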