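## broom-style tidiers for fitted objects and experiment results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an Eq 1 differentiation fit
#' @param x An `eq1_fit`.
#' @param ... Unused.
#' @return A tibble with one row per constant: `term`, `estimate`.
#' @export
tidy.eq1_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.eq1_fit
#' @export
tidy.eq2_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' One-row fit summary
#' @param x An `eq1_fit` or `eq2_fit`.
#' @param ... Unused.
#' @export
glance.eq1_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual, convergence = x$convergence,
                 at_bound = x$at_bound, nobs = nrow(x$table),
                 forward = x$forward)
}

#' @rdname glance.eq1_fit
#' @export
glance.eq2_fit <- function(x, ...) {
  tibble::tibble(residual = x$residual, convergence = x$convergence,
                 k_identifiable = x$k_identifiable, nobs = nrow(x$table),
                 forward = x$forward)
}

#' Tidy a PRCC result (one row per parameter x output)
#' @param x A `prcc_result`.
#' @param ... Unused.
#' @export
tidy.prcc_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an uncertainty experiment
#' @param x A `prcc_result`.
#' @param ... Unused.
#' @export
glance.prcc_result <- function(x, ...) {
  tibble::tibble(n_scheduled = attr(x, "n_scheduled"),
                 n_sets = nrow(attr(x, "design")),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 alpha = attr(x, "alpha"))
}

#' Tidy a treatment comparison (per-arm summary)
#' @param x A `fibrosim_treatment`.
#' @param ... Unused.
#' @export
tidy.fibrosim_treatment <- function(x, ...) {
  x$summary
}
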