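## Synthetic fixtures: shaped time series for the outcome classifier and
## closed-form dose-response tables for the calibration fitters.

#' Generate a synthetic time series of a given outcome category
#'
#' Builds a 168-h record shaped like the corresponding outcome narrative
#' (with multiplicative noise), for classifier tests and examples.
#'
#' @param kind One of `"healthy"`, `"rapid_epi_death_with_differentiation"`,
#'   `"gradual_epi_death_with_proliferation"`,
#'   `"excessive_proliferation_and_differentiation"` (short forms
#'   `"rapid"`, `"gradual"`, `"excessive"` accepted).
#' @param seed Integer seed.
#' @param n_epithelial,n_fibroblast Initial counts.
#' @param noise_sd Multiplicative noise standard deviation.
#' @return A tibble shaped like a `fibrosim_run` time series (count columns).
#' @export
make_synthetic_timeseries <- function(kind, seed = 1L, n_epithelial = 5000,
                                      n_fibroblast = 500, noise_sd = 0.02) {
  short <- c(healthy = "healthy",
             rapid = "rapid_epi_death_with_differentiation",
             gradual = "gradual_epi_death_with_proliferation",
             excessive = "excessive_proliferation_and_differentiation")
  if (kind %in% names(short)) kind <- short[[kind]]
  kind <- match.arg(kind, unname(short))
  set.seed(seed)
  t <- seq(0, 168, by = 1) # hours
  n_t <- length(t)
  noise <- function(x) pmax(0, round(x * exp(stats::rnorm(n_t, 0, noise_sd))))
  shapes <- switch(kind,
    healthy = list(
      epi = rep(n_epithelial, n_t),
      fib = rep(n_fibroblast, n_t),
      myo = rep(0, n_t)),
    rapid_epi_death_with_differentiation = list(
      epi = n_epithelial * exp(-log(2) / 10 * t),
      fib = n_fibroblast * 1.5 * exp(-log(2) / 8 * t),
      myo = n_fibroblast * 1.5 * (1 - exp(-log(2) / 8 * t))),
    gradual_epi_death_with_proliferation = list(
      epi = n_epithelial * (1 - 0.5 * t / 168),
      fib = n_fibroblast * (1 + 2 * (1 - exp(-t / 24))),
      myo = 0.02 * n_fibroblast * t / 168),
    excessive_proliferation_and_differentiation = list(
      epi = n_epithelial * exp(-log(2) / 30 * t),
      fib = n_fibroblast * 5 * stats::plogis((t - 60) / 15) *
        (1 - stats::plogis((t - 120) / 10)) + n_fibroblast,
      myo = n_fibroblast * 5 * stats::plogis((t - 120) / 10))
  )
  epi <- noise(shapes$epi); fib <- noise(shapes$fib); myo <- noise(shapes$myo)
  epi[1] <- n_epithelial; fib[1] <- n_fibroblast; myo[1] <- 0
  tibble::tibble(
    time_h = t, fibroblasts = fib, myofibroblasts = myo, epithelial = epi,
    active_tgfb1_ng = 0, latent_tgfb1_ng = 0, pge2_nmol = 0, ecm = 0,
    cum_divisions = cummax(pmax(0, fib + myo - (fib[1] + myo[1]))),
    cum_differentiations = cummax(myo),
    cum_epithelial_deaths = cummax(n_epithelial - epi),
    cum_myofibroblast_deaths = 0)
}

#' Generate a synthetic dose-response table from the closed-form maps
#'
#' Evaluates the deterministic expected 24-h response implied by the
#' per-step rules (see [predict_differentiation_fraction()] and
#' [predict_apoptosis_fraction()]) at the supplied constants and adds
#' truncated Gaussian noise.
#'
#' @param model `"eq1"` (differentiation) or `"eq2"` (apoptosis).
#' @param true_params Named list: `slope`, `a_max` for eq1; `m`, `k`, `C`
#'   for eq2.
#' @param doses Dose vector (ng/ml active TGF-beta1).
#' @param noise_sd Gaussian noise SD (response scale); responses are clamped
#'   to [0, 1].
#' @param seed Integer seed.
#' @param config Protocol configuration.
#' @param n_replicates Rows per dose.
#' @param n_cells Reported cells per replicate.
#' @return A tibble: `dose`, `response`, `n`, `replicate`.
#' @export
make_synthetic_dose_response <- function(model = c("eq1", "eq2"), true_params,
                                         doses = c(0, 0.1, 0.5, 1, 2, 4),
                                         noise_sd = 0, seed = 1L,
                                         config = reduced_config(),
                                         n_replicates = 3, n_cells = 550) {
  model <- match.arg(model)
  set.seed(seed)
  mu <- if (model == "eq1")
    predict_differentiation_fraction(doses, config,
                                     slope = true_params$slope,
                                     a_max = true_params$a_max)
  else
    predict_apoptosis_fraction(doses, config, m = true_params$m,
                               k = true_params$k, C = true_params$C)
  purrr::map_dfr(seq_len(n_replicates), function(r)
    tibble::tibble(
      dose = doses,
      response = pmin(1, pmax(0, mu + stats::rnorm(length(doses), 0, noise_sd))),
      n = n_cells, replicate = r))
}
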