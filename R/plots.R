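# ggplot2 views of the main result types.

#' Plot SASA series per design
#'
#' One line per design over time; the canonical view of how compaction
#' drives SASA down.
#'
#' @param sasa_table Tibble `design_id`, `timestep`, `sasa`.
#' @return A ggplot object.
#' @export
plot_sasa_series <- function(sasa_table) {
  ggplot2::ggplot(sasa_table,
                  ggplot2::aes(x = .data$timestep, y = .data$sasa,
                               colour = .data$design_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timestep (ns)", y = expression(SASA ~ (ring(A)^2)),
                  colour = "design") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_sasa_series autoplot method for datasets.
#' @param object An `np_dataset`.
#' @param ... Unused.
#' @export
autoplot.np_dataset <- function(object, ...) {
  plot_sasa_series(object$sasa)
}

#' Per-feature error profile of a trained ensemble
#'
#' Bar per descriptor feature with the mean error as a dashed line.
#'
#' @param object An `mbtr_forecaster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mbtr_forecaster <- function(object, ...) {
  rep <- object$report
  rep$feature <- factor(rep$feature, levels = rep$feature)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$feature, y = .data$mae)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(rep$mae), linetype = "dashed") +
    ggplot2::labs(x = "descriptor feature", y = "MAE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Window-sweep summary plot
#'
#' One-step forecaster MAE and combined SASA error against window size.
#'
#' @param object A [window_sweep()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("ensemble_mae", "error_sasa"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$w_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(w[s]), y = NULL) +
    ggplot2::theme_minimal()
}

#' Element-pair importance plot
#'
#' Horizontal bars in rank order; red for pairs pushing the predicted SASA
#' up, blue for pairs pushing it down.
#'
#' @param object An `attribution_report`.
#' @param top_n Number of leading pairs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attribution_report <- function(object, top_n = 15, ...) {
  d <- utils::head(tibble::as_tibble(object), top_n)
  d$pair <- factor(d$pair, levels = rev(d$pair))
  ggplot2::ggplot(d, ggplot2::aes(x = abs(.data$score), y = .data$pair,
                                  fill = factor(.data$sign))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`-1` = "steelblue", `0` = "grey",
                                          `1` = "firebrick"),
                               labels = c(`-1` = "lowers SASA",
                                          `0` = "neutral",
                                          `1` = "raises SASA")) +
    ggplot2::labs(x = "|mean Shapley contribution|", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
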