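## ggplot2 visualizations for simulation runs, dose responses, PRCC tables
## and treatment comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cell counts over time for a simulation run
#' @param object A `fibrosim_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fibrosim_run <- function(object, ...) {
  long <- object$timeseries |>
    dplyr::select("time_h", "fibroblasts", "myofibroblasts", "epithelial") |>
    tidyr::pivot_longer(-"time_h", names_to = "cell_type", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_h, .data$count,
                                     colour = .data$cell_type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "cells",
                  colour = NULL, title = "Simulated co-culture") +
    ggplot2::theme_minimal()
}

#' Bar chart of PRCC values by output
#' @param object A `prcc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prcc_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$prcc,
                                  stats::reorder(.data$parameter, abs(.data$prcc)),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$output)) +
    ggplot2::labs(x = "PRCC", y = NULL) +
    ggplot2::theme_minimal()
}

#' Dose-response data with the fitted curve
#' @param object An `eq1_fit` or `eq2_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eq1_fit <- function(object, ...) {
  doses <- sort(unique(object$table$dose))
  fitted <- tibble::tibble(
    dose = doses,
    response = predict_differentiation_fraction(
      doses, object$config, slope = object$par[["slope"]],
      a_max = object$par[["a_max"]]))
  plot_dose_response_fit(object$table, fitted, "fraction differentiated (24 h)")
}

#' @rdname autoplot.eq1_fit
#' @export
autoplot.eq2_fit <- function(object, ...) {
  doses <- sort(unique(object$table$dose))
  fitted <- tibble::tibble(
    dose = doses,
    response = predict_apoptosis_fraction(
      doses, object$config, m = object$par[["m"]], k = object$par[["k"]],
      C = object$par[["C"]]))
  plot_dose_response_fit(object$table, fitted, "fraction apoptotic (24 h)")
}

plot_dose_response_fit <- function(table, fitted, ylab) {
  ggplot2::ggplot(table, ggplot2::aes(.data$dose, .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fitted, colour = "steelblue") +
    ggplot2::labs(x = "initial active TGF-b1 (ng/ml)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Fold-change proliferation plot
#' @param x A `fibrosim_prolif` from [run_proliferation_checks()].
#' @return A ggplot faceted by mediator.
#' @export
plot_proliferation_checks <- function(x) {
  stopifnot(inherits(x, "fibrosim_prolif"))
  ggplot2::ggplot(x$runs, ggplot2::aes(factor(.data$dose), .data$fold_change)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$mediator), scales = "free_x") +
    ggplot2::labs(x = "dose", y = "48-h fold change in fibroblast count") +
    ggplot2::theme_minimal()
}
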