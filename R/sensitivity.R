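## Latin hypercube sampling over parameter ranges and partial rank
## correlation (PRCC) sensitivity analysis of the day-7 cell counts.

#' Default LHS parameter ranges
#'
#' One row per varied mechanism: all named mechanisms of the sensitivity
#' vocabulary (see [mechanism_aliases()]), spanning two orders of magnitude
#' centred on the configured baseline (log-uniform for rate-like
#' quantities; linear for probabilities and bounded thresholds), plus an
#' inert dummy control. Initial conditions and diffusivities are not varied.
#'
#' @param config Configuration supplying the baselines.
#' @return A tibble: `name`, `baseline`, `lower`, `upper`, `scale`.
#' @export
default_parameter_ranges <- function(config = sim_config()) {
  linear_keys <- c("agents.p_move", "agents.min_prolifTGFB1", "agents.p_myo_apop")
  al <- mechanism_aliases()
  purrr::map_dfr(al$key, function(key) {
    b <- param_get(config, key)
    if (key == "control.dummy")
      return(tibble::tibble(name = key, baseline = 1, lower = 0.1, upper = 10,
                            scale = "log"))
    if (key == "agents.min_prolifTGFB1" && b == 0)
      return(tibble::tibble(name = key, baseline = 0, lower = 0, upper = 0.2,
                            scale = "linear"))
    if (key %in% linear_keys) {
      up <- if (key == "agents.p_move") min(1, b * 10) else b * 10
      tibble::tibble(name = key, baseline = b, lower = b / 10, upper = up,
                     scale = "linear")
    } else {
      tibble::tibble(name = key, baseline = b, lower = b / 10, upper = b * 10,
                     scale = "log")
    }
  })
}

#' Latin hypercube sample of parameter vectors
#'
#' Each parameter's `n_sets` values occupy distinct equal-probability strata
#' of its (log- or linear-) uniform range with within-stratum jitter;
#' deterministic given the seed.
#'
#' @param ranges Tibble as returned by [default_parameter_ranges()].
#' @param n_sets Number of parameter sets (>= 2).
#' @param seed Integer seed.
#' @return A tibble with `n_sets` rows, one column per parameter, plus a
#'   `set_id` column.
#' @export
lhs_sample <- function(ranges, n_sets, seed = 1L) {
  stopifnot(n_sets >= 2)
  bad <- ranges$lower >= ranges$upper |
    (ranges$scale == "log" & ranges$lower <= 0)
  if (any(bad))
    stop("invalid range for parameter(s): ",
         paste(ranges$name[bad], collapse = ", "), call. = FALSE)
  set.seed(seed)
  u <- lhs::randomLHS(n_sets, nrow(ranges))
  vals <- purrr::imap_dfc(stats::setNames(seq_len(nrow(ranges)), ranges$name),
                          function(ci, nm) {
    r <- ranges[ci, ]
    x <- if (r$scale == "log")
      exp(log(r$lower) + u[, ci] * (log(r$upper) - log(r$lower)))
    else
      r$lower + u[, ci] * (r$upper - r$lower)
    tibble::tibble(!!nm := x)
  })
  dplyr::bind_cols(tibble::tibble(set_id = seq_len(n_sets)), vals)
}

#' Partial rank correlation coefficients with t-test significance
#'
#' Rank-transforms the design matrix and output, then correlates the
#' residuals of each parameter's ranks and the output's ranks after linear
#' adjustment for all other parameters. Significance uses
#' `t = r sqrt((N - 2 - p) / (1 - r^2))` with a two-sided p-value, where `p`
#' is the number of adjusted covariates.
#'
#' @param X Matrix or data frame of parameter values (rows = runs).
#' @param y Output vector, `length(y) == nrow(X)`.
#' @param output Optional output name recorded in the result.
#' @return A tibble: `parameter`, `output`, `prcc`, `statistic`, `p_value`,
#'   `n_effective`. Constant columns yield `NA` coefficients with a warning.
#' @export
prcc <- function(X, y, output = "output") {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  npar <- ncol(X)
  if (nrow(X) < npar + 3)
    stop("need at least #parameters + 3 observations", call. = FALSE)
  const <- vapply(X, function(col) stats::var(col) == 0, logical(1))
  if (any(const))
    warning("constant parameter column(s): ",
            paste(names(X)[const], collapse = ", "), call. = FALSE)
  Xr <- vapply(X, rank, numeric(nrow(X)))
  yr <- rank(y)
  N <- nrow(X)
  purrr::map_dfr(seq_len(npar), function(j) {
    if (const[j])
      return(tibble::tibble(parameter = names(X)[j], output = output,
                            prcc = NA_real_, statistic = NA_real_,
                            p_value = NA_real_, n_effective = N))
    others <- Xr[, setdiff(which(!const), j), drop = FALSE]
    if (ncol(others) > 0) {
      rx <- stats::lm.fit(cbind(1, others), Xr[, j])$residuals
      ry <- stats::lm.fit(cbind(1, others), yr)$residuals
    } else {
      rx <- Xr[, j] - mean(Xr[, j]); ry <- yr - mean(yr)
    }
    r <- suppressWarnings(stats::cor(rx, ry))
    p_adj <- ncol(others)
    df <- N - 2 - p_adj
    tstat <- r * sqrt(df / max(1e-12, 1 - r^2))
    tibble::tibble(parameter = names(X)[j], output = output, prcc = r,
                   statistic = tstat,
                   p_value = 2 * stats::pt(-abs(tstat), df), n_effective = N)
  })
}

#' Run the LHS/PRCC uncertainty experiment
#'
#' Simulates `n_sets` Latin-hypercube parameter sets, each in
#' `n_replicates` stochastic replicates, and computes PRCCs of the
#' fibroblast, myofibroblast and epithelial counts at the evaluation day.
#' Replicate outputs are averaged per set before ranking, so the effective
#' sample size of the t-test is `n_sets`.
#'
#' @param ranges Parameter ranges tibble (default:
#'   [default_parameter_ranges()] of `config`).
#' @param config Base configuration (use [reduced_config()] for desk scale).
#' @param n_sets Number of LHS parameter sets.
#' @param n_replicates Stochastic replicates per set.
#' @param seed Master seed for the design and all run seeds.
#' @param eval_day Evaluation time, days.
#' @param alpha Significance threshold on the PRCC p-values.
#' @param dry_run If `TRUE`, build the design and run schedule without
#'   simulating; returns a list with `design`, `n_scheduled` and `run_seeds`.
#' @return A `prcc_result` object: tibble of PRCC rows (all outputs) with
#'   attributes `design` (the LHS sample), `outputs` (per-set averaged
#'   outputs), `n_scheduled` (total runs), `alpha`.
#' @export
run_uncertainty_experiment <- function(ranges = NULL, config = reduced_config(),
                                       n_sets = 60, n_replicates = 3,
                                       seed = 1L, eval_day = 7, alpha = 0.01,
                                       dry_run = FALSE) {
  if (is.null(ranges)) ranges <- default_parameter_ranges(config)
  design <- lhs_sample(ranges, n_sets, seed)
  if (dry_run) {
    set.seed(seed + 1L)
    run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                   n_sets * n_replicates), nrow = n_sets)
    return(list(design = design, n_scheduled = n_sets * n_replicates,
                run_seeds = run_seeds))
  }
  set.seed(seed + 1L)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 n_sets * n_replicates),
                      nrow = n_sets)
  pnames <- ranges$name
  outputs <- purrr::map_dfr(seq_len(n_sets), function(si) {
    cfg <- config
    for (nm in pnames) cfg <- param_set(cfg, nm, design[[nm]][si])
    cfg$run$duration_h <- eval_day * 24
    reps <- purrr::map_dfr(seq_len(n_replicates), function(ri) {
      cfg$run$seed <- run_seeds[si, ri]
      ts <- run_simulation(cfg, keep_state = FALSE)$timeseries
      last <- ts[which.min(abs(ts$time_h - eval_day * 24)), ]
      tibble::tibble(fibroblasts = last$fibroblasts,
                     myofibroblasts = last$myofibroblasts,
                     epithelial = last$epithelial)
    })
    dplyr::summarise(reps, dplyr::across(dplyr::everything(), mean))
  })
  X <- as.data.frame(design[pnames])
  res <- purrr::map_dfr(names(outputs), function(out)
    prcc(X, outputs[[out]], output = out))
  res$significant <- !is.na(res$p_value) & res$p_value < alpha
  structure(res, class = c("prcc_result", class(res)),
            design = design, outputs = outputs,
            n_scheduled = n_sets * n_replicates, alpha = alpha)
}

#' @export
print.prcc_result <- function(x, ...) {
  cat("<prcc_result> ", attr(x, "n_scheduled"), " scheduled runs; PRCCs at p < ",
      attr(x, "alpha"), ":\n", sep = "")
  NextMethod()
}
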