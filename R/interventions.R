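## Virtual treatment experiments: single-mechanism and combined ("two-hit")
## parameter perturbations applied at t = 0 to poor-outcome scenarios, with
## matched-seed rescue evaluation.

#' Define an intervention as a set of parameter multipliers
#'
#' @param ... Named multipliers, e.g.
#'   `intervention_spec("molecular.k_synL" = 0.1)`; names are flat config
#'   keys or mechanism names (see [mechanism_aliases()]).
#' @param label Intervention label (defaults to a compact description).
#' @return An `intervention_spec` tibble with columns `parameter`,
#'   `multiplier` and attribute `label`.
#' @export
intervention_spec <- function(..., label = NULL) {
  mult <- c(...)
  if (length(mult) == 0) {
    spec <- tibble::tibble(parameter = character(0), multiplier = numeric(0))
  } else {
    if (is.null(names(mult)) || any(!nzchar(names(mult))))
      stop("multipliers must be named by parameter", call. = FALSE)
    if (any(mult <= 0)) stop("multipliers must be > 0", call. = FALSE)
    spec <- tibble::tibble(parameter = names(mult), multiplier = unname(mult))
  }
  if (is.null(label))
    label <- if (nrow(spec) == 0) "untreated" else
      paste(sprintf("%s x%g", spec$parameter, spec$multiplier), collapse = ", ")
  structure(spec, class = c("intervention_spec", class(spec)), label = label)
}

#' Apply an intervention to a configuration
#'
#' Returns a copy of the configuration with each named parameter multiplied;
#' the original is untouched. Applying two specs in sequence equals applying
#' their concatenation.
#'
#' @param config A `fibrosim_config`.
#' @param spec An [intervention_spec()].
#' @return The modified configuration.
#' @export
apply_intervention <- function(config, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  for (r in seq_len(nrow(spec)))
    config <- param_set(config, spec$parameter[r],
                        param_get(config, spec$parameter[r]) * spec$multiplier[r])
  config
}

#' Load a shipped dysregulated-culture scenario preset
#'
#' The three presets are constructed parameterizations of the reduced
#' co-culture that land in the corresponding non-healthy outcome category:
#' `"rapid"` (rapid epithelial death with differentiation), `"gradual"`
#' (gradual epithelial death with fibroblast proliferation) and
#' `"excessive"` (excessive proliferation and differentiation). Presets are
#' plain-text config overlays under `inst/extdata/`.
#'
#' @param name Scenario name.
#' @return A `fibrosim_config`.
#' @export
scenario_config <- function(name = c("rapid", "gradual", "excessive")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("scenario_", name, ".cfg"),
                      package = "fibrosim", mustWork = TRUE)
  load_config(path, base = reduced_config())
}

# the paper's intervention pairs per scenario
scenario_interventions <- function(name, down = 0.1, up = 10) {
  if (name %in% c("rapid", "gradual"))
    list(
      intervention_spec("TGF-b1 synthesis" = down, label = "decreased TGF-b1 synthesis"),
      intervention_spec("PGE2 synthesis" = up, label = "increased PGE2 synthesis"),
      intervention_spec("TGF-b1 synthesis" = down, "PGE2 synthesis" = up,
                        label = "combined")
    )
  else
    list(
      intervention_spec("TGF-b1 synthesis" = down, label = "decreased TGF-b1 synthesis"),
      intervention_spec("TGF-b1 activation" = down, label = "decreased TGF-b1 activation"),
      intervention_spec("TGF-b1 synthesis" = down, "TGF-b1 activation" = down,
                        label = "combined")
    )
}

#' Run a matched-seed treatment comparison
#'
#' Simulates the untreated scenario and each intervention with the same
#' stochastic seeds and reports paired endpoint metrics: epithelial survival
#' fraction at 168 h, peak fibroblast fold-change, final myofibroblast
#' fraction of the fibroblast lineage, and the outcome class.
#'
#' @param config Scenario configuration (should classify as non-healthy
#'   untreated).
#' @param specs List of [intervention_spec()] objects.
#' @param seeds Integer vector of matched seeds.
#' @return A `fibrosim_treatment` object: list with `runs` (one row per
#'   arm x seed) and `summary` (per-arm means; the untreated arm first).
#' @export
run_treatment_comparison <- function(config, specs, seeds = 1:10) {
  arms <- c(list(intervention_spec(label = "untreated")), specs)
  runs <- purrr::map_dfr(arms, function(sp) {
    cfg0 <- apply_intervention(config, sp)
    purrr::map_dfr(seeds, function(s) {
      cfg <- cfg0
      cfg$run$seed <- as.integer(s)
      ts <- run_simulation(cfg, keep_state = FALSE)$timeseries
      end <- ts[which.min(abs(ts$time_h - 168)), ]
      epi0 <- ts$epithelial[1]; fib0 <- max(1, ts$fibroblasts[1])
      lineage <- end$fibroblasts + end$myofibroblasts
      tibble::tibble(
        label = attr(sp, "label"), seed = s,
        epithelial_survival = if (epi0 > 0) end$epithelial / epi0 else 1,
        peak_fibroblast_fold = max(ts$fibroblasts) / fib0,
        final_myofibroblast_fraction =
          if (lineage > 0) end$myofibroblasts / lineage else 0,
        outcome = classify_outcome(ts))
    })
  })
  sm <- runs |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      epithelial_survival = mean(.data$epithelial_survival),
      peak_fibroblast_fold = mean(.data$peak_fibroblast_fold),
      final_myofibroblast_fraction = mean(.data$final_myofibroblast_fraction),
      modal_outcome = names(sort(table(.data$outcome), decreasing = TRUE))[1],
      .groups = "drop") |>
    dplyr::arrange(.data$label != "untreated")
  structure(list(runs = runs, summary = sm, seeds = seeds),
            class = "fibrosim_treatment")
}

#' Does the combined intervention dominate the single interventions?
#'
#' Evaluates, seed by matched seed, whether the combined arm's epithelial
#' survival at 168 h is at least the better single intervention's survival.
#'
#' @param x A `fibrosim_treatment` whose arms include a `"combined"` label
#'   and at least one other treated arm.
#' @return A list: `n_seeds`, `n_dominant`, `majority` (logical).
#' @export
two_hit_dominance <- function(x) {
  stopifnot(inherits(x, "fibrosim_treatment"))
  wide <- x$runs |>
    dplyr::select("label", "seed", "epithelial_survival") |>
    tidyr::pivot_wider(names_from = "label", values_from = "epithelial_survival")
  singles <- setdiff(names(wide), c("seed", "untreated", "combined"))
  if (!"combined" %in% names(wide) || length(singles) == 0)
    stop("comparison must include a 'combined' arm and single arms",
         call. = FALSE)
  best_single <- do.call(pmax, wide[singles])
  dom <- wide$combined >= best_single - 1e-12
  list(n_seeds = nrow(wide), n_dominant = sum(dom),
       majority = sum(dom) > nrow(wide) / 2)
}

#' @export
print.fibrosim_treatment <- function(x, ...) {
  cat("<fibrosim_treatment> ", length(x$seeds), " matched seeds\n", sep = "")
  print(x$summary)
  invisible(x)
}
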