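# Shapley-style explanation of SASA predictions. Per-feature signed
# contributions are computed either exactly (path-dependent tree explainer,
# for the boosted models) or by a sampling kernel estimator (any model),
# then aggregated from grid-point features into per-element-pair scores and
# ranked by magnitude.

#' Per-residue descriptor dataset
#'
#' Encodes the atoms of one residue type in isolation (same descriptor
#' configuration as the whole system) and pairs each row with the design's
#' total SASA at that timestep — the inputs for a residue-specific
#' explanation model.
#'
#' @param trajectory Long atom table covering one or more designs.
#' @param residue_name Residue code to isolate (e.g. `"PAN"`).
#' @param cfg [mbtr_config()].
#' @param sasa_table Tibble `design_id`, `timestep`, `sasa` for the whole
#'   systems.
#' @return List with `mbtr` (descriptor tibble of the residue subset) and
#'   `sasa` (matching rows of `sasa_table`).
#' @export
per_residue_dataset <- function(trajectory, residue_name,
                                cfg = mbtr_config(), sasa_table) {
  sub <- residue_subset(trajectory, residue_name)
  enc <- encode_trajectory(sub, cfg)
  sasa <- dplyr::semi_join(sasa_table, enc, by = c("design_id", "timestep"))
  if (nrow(sasa) != nrow(enc)) {
    abort("SASA table does not cover every encoded snapshot")
  }
  list(mbtr = enc, sasa = dplyr::arrange(sasa, .data$design_id,
                                         .data$timestep))
}

#' Shapley-style per-feature attributions
#'
#' For tree-backed models (`sasa_gbm`) the exact path-dependent tree
#' explainer is used; for any other model a sampling kernel estimator
#' regresses the model output on feature-coalition masks under the Shapley
#' kernel weighting, with missing features marginalised over the background
#' set. In both cases the attributions satisfy local additivity:
#' `baseline + sum(contributions) ~ prediction` for every explained row.
#'
#' @param model A fitted SASA model ([train_sasa_model()]), any object with
#'   a [predict_sasa()] method, or a plain function mapping a numeric matrix
#'   of rows to a numeric vector of predictions.
#' @param background Background rows (matrix or descriptor tibble); down-
#'   sampled to at most `max_background` rows, seeded.
#' @param explain Rows to explain (matrix or descriptor tibble).
#' @param n_coalitions Sampled feature coalitions per row for the kernel
#'   estimator (ignored by the tree path).
#' @param max_background Background subsample cap.
#' @param seed RNG seed for subsampling and coalition draws.
#' @return Object of class `shap_values`: `values` (rows x features signed
#'   matrix), `baseline` (expected model output over the background), and
#'   `predictions`.
#' @export
shapley_attribution <- function(model, background, explain,
                                n_coalitions = 1000, max_background = 200,
                                seed = 1L) {
  bg <- if (is.data.frame(background)) .feature_matrix(background)
        else as.matrix(background)
  ex <- if (is.data.frame(explain)) .feature_matrix(explain)
        else as.matrix(explain)
  stopifnot(nrow(bg) >= 1, nrow(ex) >= 1)
  withr::local_seed(seed)
  if (nrow(bg) > max_background) {
    bg <- bg[sample.int(nrow(bg), max_background), , drop = FALSE]
  }
  pred_fun <- if (is.function(model)) model
              else function(m) predict_sasa(model, m)
  if (inherits(model, "sasa_gbm")) {
    contrib <- predict(model$booster, xgboost::xgb.DMatrix(ex),
                       predcontrib = TRUE)
    values <- contrib[, -ncol(contrib), drop = FALSE]
    baseline <- contrib[1, ncol(contrib)]
  } else {
    ks <- .kernel_shap(pred_fun, bg, ex, n_coalitions)
    values <- ks$values
    baseline <- ks$baseline
  }
  colnames(values) <- paste0("f", seq_len(ncol(values)) - 1L)
  structure(list(values = values, baseline = baseline,
                 predictions = as.vector(pred_fun(ex))),
            class = "shap_values")
}

# Kernel estimator: sample coalitions z in {0,1}^M with |z| drawn from the
# Shapley kernel profile, evaluate v(z) = mean over background rows of the
# model with masked features imputed from the background, and solve the
# weighted least squares with the efficiency constraint
# sum(phi) = f(x) - baseline eliminated by substitution.
.kernel_shap <- function(f, bg, ex, n_coalitions) {
  M <- ncol(ex)
  baseline <- mean(f(bg))
  sizes <- seq_len(M - 1)
  kw <- (M - 1) / (choose(M, sizes) * sizes * (M - sizes))
  size_p <- choose(M, sizes) * kw          # marginal weight of each |z|
  size_p <- size_p / sum(size_p)

  n_bg <- nrow(bg)
  values <- matrix(0, nrow(ex), M)
  for (r in seq_len(nrow(ex))) {
    x <- ex[r, ]
    fx <- mean(f(matrix(x, 1)))
    draw_sizes <- sample(sizes, n_coalitions, replace = TRUE, prob = size_p)
    Z <- matrix(0L, n_coalitions, M)
    for (i in seq_len(n_coalitions)) {
      Z[i, sample.int(M, draw_sizes[i])] <- 1L
    }
    # v(z): average model output with masked features drawn from background
    v <- numeric(n_coalitions)
    for (i in seq_len(n_coalitions)) {
      Xb <- bg
      on <- Z[i, ] == 1L
      Xb[, on] <- matrix(x[on], n_bg, sum(on), byrow = TRUE)
      v[i] <- mean(f(Xb))
    }
    w <- kw[draw_sizes]
    # eliminate phi_M via the efficiency constraint
    y <- v - baseline - Z[, M] * (fx - baseline)
    A <- Z[, -M, drop = FALSE] - Z[, M]
    WA <- A * w
    beta <- tryCatch(solve(crossprod(WA, A), crossprod(WA, y)),
                     error = function(e) {
                       qr.solve(crossprod(WA, A) + diag(1e-8, M - 1),
                                crossprod(WA, y))
                     })
    phi <- c(as.vector(beta), fx - baseline - sum(beta))
    values[r, ] <- phi
  }
  list(values = values, baseline = baseline)
}

#' Aggregate per-feature attributions into an element-pair report
#'
#' The mean signed contribution of each feature across the explained rows
#' is averaged over the grid points of its element-pair block, giving one
#' signed importance per pair; pairs are ranked by decreasing magnitude
#' with the sign carried through (positive = raises the predicted SASA).
#'
#' @param shap A `shap_values` object (or bare rows x features matrix).
#' @param cfg The [mbtr_config()] the features were encoded with.
#' @param residue_name Optional residue label carried into the report.
#' @return Tibble of class `attribution_report`: `rank`, `pair`, `score`,
#'   `sign`; attribute `baseline_value` holds the background expectation.
#' @export
rank_pairs <- function(shap, cfg = mbtr_config(), residue_name = NA) {
  values <- if (inherits(shap, "shap_values")) shap$values else as.matrix(shap)
  info <- mbtr_feature_info(cfg)
  if (ncol(values) != nrow(info)) {
    abort(paste0("attribution matrix has ", ncol(values),
                 " columns but the configuration implies ", nrow(info),
                 " features"))
  }
  per_feature <- colMeans(values)
  tbl <- info |>
    dplyr::mutate(value = per_feature) |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(score = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(abs(.data$score))) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  sign = sign(.data$score),
                  residue_name = residue_name) |>
    dplyr::select("rank", "pair", "score", "sign", "residue_name")
  structure(tbl, class = c("attribution_report", class(tbl)),
            baseline_value = if (inherits(shap, "shap_values"))
              shap$baseline else NA_real_)
}
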