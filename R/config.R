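## Simulation configuration: defaults, validation, flat dotted-key plain-text
## serialization, and the mechanism-name aliases used by the sensitivity and
## intervention modules.

#' Build a simulation configuration
#'
#' Returns the complete nested configuration with the baseline parameter
#' values. Any component can be overridden by passing a named list, e.g.
#' `sim_config(init = list(n_fibroblast = 100), run = list(duration_h = 48))`.
#'
#' @param grid,env,molecular,agents,init,run,control Named lists of overrides
#'   for the corresponding component.
#' @return A `fibrosim_config` object.
#' @export
#' @examples
#' cfg <- sim_config(run = list(duration_h = 24, seed = 7))
#' cfg$run$duration_h
sim_config <- function(grid = list(), env = list(), molecular = list(),
                       agents = list(), init = list(), run = list(),
                       control = list()) {
  base <- list(
    grid = list(nx = 81L, ny = 81L, nz = 282L, dx_um = 22),
    env = list(D_tgfb1_cm2_s = 2e-7, D_pge2_cm2_s = 5e-6,
               halflife_active_min = 2.7, halflife_latent_min = 9.2,
               halflife_pge2_min = 360, k_act_per_min = 0.01),
    molecular = unclass(molecular_params()),
    agents = unclass(agent_params()),
    init = list(n_epithelial = 5000L, n_fibroblast = 500L,
                initial_activeTGFB1 = 0, initial_PGE2 = 0,
                receptors_per_cell = NA_real_),
    run = list(duration_h = 168, dt_abm_min = 10, record_every_min = 60,
               n_mol_substeps = NA_integer_, diffusion_method = "implicit",
               n_diff_substeps = 1L, clamp_tgfb1 = NA_real_,
               clamp_pge2 = NA_real_, seed = 1L),
    control = list(dummy = 1) # inert; LHS negative control
  )
  ov <- list(grid = grid, env = env, molecular = molecular, agents = agents,
             init = init, run = run, control = control)
  for (sec in names(ov)) {
    bad <- setdiff(names(ov[[sec]]), names(base[[sec]]))
    if (length(bad))
      stop("unknown config key(s): ", paste0(sec, ".", bad, collapse = ", "),
           call. = FALSE)
    base[[sec]][names(ov[[sec]])] <- ov[[sec]]
  }
  validate_config(structure(base, class = "fibrosim_config"))
}

validate_config <- function(config) {
  g <- do.call(grid_spec, config$grid)  # validates grid
  do.call(molecular_params, config$molecular)
  do.call(agent_params, config$agents)
  ini <- config$init
  if (ini$n_epithelial < 0 || ini$n_fibroblast < 0)
    stop("initial cell counts must be nonnegative", call. = FALSE)
  if (ini$n_epithelial + ini$n_fibroblast > compartments_per_layer(g))
    stop("requested cells exceed surface capacity (",
         compartments_per_layer(g), " voxels)", call. = FALSE)
  if (ini$initial_activeTGFB1 < 0 || ini$initial_PGE2 < 0)
    stop("initial concentrations must be nonnegative", call. = FALSE)
  if (config$run$duration_h <= 0) stop("duration must be > 0", call. = FALSE)
  if (config$run$dt_abm_min <= 0) stop("ABM step must be > 0", call. = FALSE)
  if (!config$run$diffusion_method %in% c("implicit", "ftcs"))
    stop("diffusion_method must be 'implicit' or 'ftcs'", call. = FALSE)
  config
}

#' Reduced desk-scale configuration preset
#'
#' A 27 x 27 x 20 lattice seeded with 550 epithelial cells and 55
#' fibroblasts (the full model's areal densities); used for all stochastic
#' desk-scale experiments.
#'
#' @inheritParams sim_config
#' @return A `fibrosim_config`.
#' @export
reduced_config <- function(grid = list(), env = list(), molecular = list(),
                           agents = list(), init = list(), run = list(),
                           control = list()) {
  sim_config(
    grid = utils::modifyList(list(nx = 27L, ny = 27L, nz = 20L), grid),
    env = env, molecular = molecular, agents = agents,
    init = utils::modifyList(list(n_epithelial = 550L, n_fibroblast = 55L),
                             init),
    run = run, control = control)
}

## ---- flat key-value serialization -------------------------------------

config_flatten <- function(config) {
  out <- list()
  for (sec in names(config))
    for (key in names(config[[sec]]))
      out[[paste0(sec, ".", key)]] <- config[[sec]][[key]]
  out
}

#' Write a configuration as flat `key = value` text
#' @param config A `fibrosim_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fl <- config_flatten(config)
  fmt <- function(v) {
    if (is.character(v)) v else format(v, digits = 17, scientific = NA)
  }
  writeLines(paste(names(fl), "=", vapply(fl, fmt, character(1))), path)
  invisible(path)
}

#' Load a configuration from flat `key = value` text
#'
#' Unknown keys are an error; keys missing from the file keep their baseline
#' defaults, so an empty file yields the full default configuration.
#'
#' @param path Path to the config file.
#' @param base Base configuration the file overrides (default the full-scale
#'   baseline).
#' @return A `fibrosim_config`.
#' @export
load_config <- function(path, base = sim_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ov <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(base) ||
        !parts[2] %in% names(base[[parts[1]]]))
      stop("unknown config key: ", key, call. = FALSE)
    old <- base[[parts[1]]][[parts[2]]]
    parsed <- if (is.character(old)) val else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) && !identical(toupper(val), "NA"))
        stop("bad value for ", key, ": ", val, call. = FALSE)
      if (is.integer(old) && !is.na(num)) as.integer(num) else num
    }
    ov[[parts[1]]][[parts[2]]] <- parsed
  }
  args <- ov[lengths(ov) > 0]
  cfg <- base
  for (sec in names(args)) cfg[[sec]][names(args[[sec]])] <- args[[sec]]
  validate_config(cfg)
}

## ---- parameter keys and mechanism aliases ------------------------------

#' Mechanism names and the configuration entries that house them
#'
#' Maps each named mechanism of the cellular/molecular model (the
#' sensitivity analysis vocabulary) to its flat configuration key.
#'
#' @return A tibble with columns `mechanism` and `key`.
#' @export
mechanism_aliases <- function() {
  tibble::tribble(
    ~mechanism,                                        ~key,
    "TGF-b1 synthesis",                                "molecular.k_synL",
    "PGE2 synthesis",                                  "agents.V_ePGE2",
    "TGF-b1 activation",                               "env.k_act_per_min",
    "TGF-b1 receptor dissociation",                    "molecular.k_off",
    "Fibroblast insensitivity to TGF-b1",              "molecular.K_S",
    "Fibroblast sensitivity to PGE2",                  "molecular.K_P",
    "Probability of fibroblast movement",              "agents.p_move",
    "TGF-b1 proliferation threshold",                  "agents.min_prolifTGFB1",
    "PGE2 proliferation maximum",                      "agents.max_prolifPGE2",
    "aSMA differentiation maximum",                    "agents.a_max",
    "TGF-b1 to PGE2 differentiation threshold",        "agents.ratio_diff",
    "PGE2 inhibition of TGF-b1 induced differentiation", "agents.k_inhib_diff",
    "PGE2 binding rate",                               "agents.k",
    "Epithelial cell TGF-b1 binding rate",             "agents.beta_T",
    "Epithelial cell sensitivity to PGE2",             "agents.beta_P",
    "Myofibroblast apoptosis",                         "agents.p_myo_apop",
    "ECM deposition",                                  "agents.q_ecm",
    "Dummy (inert control)",                           "control.dummy"
  )
}

# resolve "sec.key" or a mechanism name to c(section, key)
resolve_param_key <- function(key) {
  al <- mechanism_aliases()
  hit <- match(key, al$mechanism)
  if (!is.na(hit)) key <- al$key[hit]
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("unknown parameter: ", key, call. = FALSE)
  parts
}

#' Read a parameter from a configuration by flat key or mechanism name
#' @param config A `fibrosim_config`.
#' @param key Flat key (`"molecular.k_synL"`) or mechanism name.
#' @export
param_get <- function(config, key) {
  parts <- resolve_param_key(key)
  if (!parts[1] %in% names(config) || !parts[2] %in% names(config[[parts[1]]]))
    stop("unknown parameter: ", key, call. = FALSE)
  config[[parts[1]]][[parts[2]]]
}

#' Set a parameter in a configuration by flat key or mechanism name
#' @inheritParams param_get
#' @param value New value.
#' @return The modified configuration (the original is untouched).
#' @export
param_set <- function(config, key, value) {
  parts <- resolve_param_key(key)
  if (!parts[1] %in% names(config) || !parts[2] %in% names(config[[parts[1]]]))
    stop("unknown parameter: ", key, call. = FALSE)
  config[[parts[1]]][[parts[2]]] <- value
  # a_max is shared between the molecular capacity and Eq 1 normalization
  if (parts[2] == "a_max") {
    config$molecular$a_max <- value
    config$agents$a_max <- value
  }
  validate_config(config)
}

#' @export
print.fibrosim_config <- function(x, ...) {
  g <- x$grid
  cat("<fibrosim_config> ", g$nx, "x", g$ny, "x", g$nz, " voxels (dx ",
      g$dx_um, " um), ", x$init$n_epithelial, " epithelial + ",
      x$init$n_fibroblast, " fibroblasts, ", x$run$duration_h, " h\n",
      sep = "")
  invisible(x)
}
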