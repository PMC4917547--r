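## Orchestration: initialization, the multi-scale time loop, recording,
## reproducibility, and the four-category outcome classifier.
##
## Update order within one ABM step (dt = 10 min by default):
##   1. snapshot each cell's local mediator concentrations (start-of-step)
##   2. non-molecular secretion (epithelial PGE2 + latent, fibroblast PGE2)
##   3. vectorised molecular integration for the fibroblast lineage, with
##      in-step depletion of the cell's own voxel; latent deposition
##   4. cell events: epithelial death, myofibroblast death + deposition,
##      differentiation, division, movement
##   5. latent activation, latent decay, field diffusion + decay
## Cells therefore respond to the concentrations present when the step
## begins; an exogenous dose is seen for a full step before it decays.

new_world <- function(config) {
  spec <- do.call(grid_spec, config$grid)
  nsurf <- compartments_per_layer(spec)
  n_epi <- as.integer(config$init$n_epithelial)
  n_fib <- as.integer(config$init$n_fibroblast)
  n0 <- n_epi + n_fib
  if (n0 > nsurf)
    stop("requested cells exceed surface capacity (", nsurf, " voxels)",
         call. = FALSE)
  p <- do.call(molecular_params, config$molecular)
  ap <- do.call(agent_params, config$agents)

  cap <- max(16L, 2L * n0)
  w <- list(
    config = config, spec = spec, p = p, ap = ap,
    vox_ml = voxel_volume_ml(spec), vox_l = voxel_volume_l(spec),
    tgfb = array(config$init$initial_activeTGFB1,
                 dim = c(spec$nx, spec$ny, spec$nz)),
    pge2 = array(config$init$initial_PGE2,
                 dim = c(spec$nx, spec$ny, spec$nz)),
    ecm = matrix(0, spec$nx, spec$ny),
    latent = matrix(0, spec$nx, spec$ny),
    occupancy = matrix(0L, spec$nx, spec$ny),
    n = 0L,
    kind = integer(cap), ci = integer(cap), cj = integer(cap),
    alive = logical(cap), age = numeric(cap),
    mol = matrix(0, cap, MOL_NSTATE),
    B_T = numeric(cap), B_P = numeric(cap),
    counters = list(divisions = 0, differentiations = 0,
                    epithelial_deaths = 0, myofibroblast_deaths = 0),
    audit = list(secreted_latent_ng = 0, discarded_latent_ng = 0,
                 degraded_latent_ng = 0, degraded_active_ng = 0,
                 initial_active_ng = 0),
    time_min = 0
  )
  w$audit$initial_active_ng <- sum(w$tgfb) * w$vox_ml

  # uniform random placement on distinct surface voxels
  if (n0 > 0) {
    vox <- sample.int(nsurf, n0)
    i <- (vox - 1L) %% spec$nx + 1L
    j <- (vox - 1L) %/% spec$nx + 1L
    kinds <- c(rep(KIND_EPITHELIAL, n_epi), rep(KIND_FIBROBLAST, n_fib))
    w$n <- n0
    w$kind[1:n0] <- kinds
    w$ci[1:n0] <- i; w$cj[1:n0] <- j
    w$alive[1:n0] <- TRUE
    w$occupancy[cbind(i, j)] <- 1:n0
    fl <- which(kinds != KIND_EPITHELIAL)
    R0 <- config$init$receptors_per_cell
    if (is.na(R0)) R0 <- p$v_R / p$k_tR
    w$mol[fl, 1] <- R0
  }
  w$confluence <- n0 / nsurf
  w
}

grow_world <- function(w, need) {
  cap <- length(w$kind)
  if (w$n + need <= cap) return(w)
  newcap <- max(cap * 2L, w$n + need)
  pad <- newcap - cap
  w$kind <- c(w$kind, integer(pad)); w$ci <- c(w$ci, integer(pad))
  w$cj <- c(w$cj, integer(pad)); w$alive <- c(w$alive, logical(pad))
  w$age <- c(w$age, numeric(pad))
  w$mol <- rbind(w$mol, matrix(0, pad, MOL_NSTATE))
  w$B_T <- c(w$B_T, numeric(pad)); w$B_P <- c(w$B_P, numeric(pad))
  w
}

#' Initialize the virtual co-culture
#'
#' Places the configured epithelial cells and fibroblasts uniformly at
#' random on distinct plate-surface voxels and reports the resulting
#' confluence (occupied fraction of the surface).
#'
#' @param config A [sim_config()].
#' @return A world state (opaque list); its `confluence` element is the
#'   initial occupied fraction.
#' @export
initialize_culture <- function(config) {
  set.seed(config$run$seed)
  new_world(config)
}

# local field values at each cell's surface voxel (or the clamp)
local_conc <- function(w, rows) {
  clampT <- w$config$run$clamp_tgfb1
  clampP <- w$config$run$clamp_pge2
  ij1 <- cbind(w$ci[rows], w$cj[rows], 1L)
  list(
    T = if (is.na(clampT)) w$tgfb[ij1] else rep(clampT, length(rows)),
    P = if (is.na(clampP)) w$pge2[ij1] else rep(clampP, length(rows))
  )
}

MOORE_DI <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
MOORE_DJ <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)

# empty Moore neighbours of (i, j); returns matrix of (i, j) rows
empty_neighbors <- function(w, i, j) {
  ii <- i + MOORE_DI; jj <- j + MOORE_DJ
  ok <- ii >= 1L & ii <= w$spec$nx & jj >= 1L & jj <= w$spec$ny
  ii <- ii[ok]; jj <- jj[ok]
  free <- w$occupancy[ii + w$spec$nx * (jj - 1L)] == 0L
  cbind(ii[free], jj[free])
}

# pick one uniformly random empty Moore neighbour (linear occupancy index),
# or 0L if none; occ is the occupancy matrix treated as a vector
pick_empty_neighbor <- function(occ, nx, ny, i, j) {
  ii <- i + MOORE_DI; jj <- j + MOORE_DJ
  ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
  lin <- ii[ok] + nx * (jj[ok] - 1L)
  lin <- lin[occ[lin] == 0L]
  n <- length(lin)
  if (n == 0L) 0L else if (n == 1L) lin else lin[sample.int(n, 1L)]
}

step_world <- function(w, dt) {
  ap <- w$ap; p <- w$p
  clampT <- !is.na(w$config$run$clamp_tgfb1)
  clampP <- !is.na(w$config$run$clamp_pge2)
  live <- which(w$alive[seq_len(w$n)])
  kinds <- w$kind[live]
  epi <- live[kinds == KIND_EPITHELIAL]
  fib <- live[kinds == KIND_FIBROBLAST]
  myo <- live[kinds == KIND_MYOFIBROBLAST]
  fl <- c(fib, myo)

  ## 1. snapshot local concentrations
  lc_fl <- if (length(fl)) local_conc(w, fl) else list(T = numeric(0), P = numeric(0))
  lc_epi <- if (length(epi)) local_conc(w, epi) else list(T = numeric(0), P = numeric(0))

  ## 2. non-molecular secretion
  if (length(epi)) {
    if (!clampP) {
      ij <- cbind(w$ci[epi], w$cj[epi], 1L)
      w$pge2[ij] <- w$pge2[ij] + ap$V_ePGE2 * dt / w$vox_l
    }
    dep <- ap$eps_epiTGFB1 * p$k_synL * dt
    w$latent[cbind(w$ci[epi], w$cj[epi])] <-
      w$latent[cbind(w$ci[epi], w$cj[epi])] + dep
    w$audit$secreted_latent_ng <- w$audit$secreted_latent_ng + dep * length(epi)
  }
  if (length(fib) && !clampP) {
    ij <- cbind(w$ci[fib], w$cj[fib], 1L)
    w$pge2[ij] <- w$pge2[ij] + ap$eps_fibPGE2 * ap$V_ePGE2 * dt / w$vox_l
  }

  ## 3. molecular integration (fibroblast lineage), voxel depletion coupled
  dA <- numeric(0)
  if (length(fl)) {
    S <- w$mol[fl, , drop = FALSE]
    S[, 9] <- lc_fl$T
    kon <- ifelse(w$kind[fl] == KIND_MYOFIBROBLAST, p$k_onM, p$k_on)
    omega <- if (clampT) 0 else TGFB1_NG_PER_MOLECULE / w$vox_ml
    nsub <- w$config$run$n_mol_substeps
    if (is.na(nsub)) nsub <- mol_substeps(p, dt)
    S2 <- mol_rk4(S, lc_fl$P, kon, p, dt, nsub, omega)
    if (any(!is.finite(S2)))
      stop("molecular integration failed at t = ", w$time_min, " min",
           call. = FALSE)
    dA <- S2[, 5] - S[, 5]
    dsec <- S2[, 8] - S[, 8]
    if (!clampT) w$tgfb[cbind(w$ci[fl], w$cj[fl], 1L)] <- pmax(0, S2[, 9])
    dep <- ap$f_lat_surface * dsec
    w$latent[cbind(w$ci[fl], w$cj[fl])] <-
      w$latent[cbind(w$ci[fl], w$cj[fl])] + dep
    w$audit$secreted_latent_ng <- w$audit$secreted_latent_ng + sum(dep)
    w$audit$discarded_latent_ng <- w$audit$discarded_latent_ng +
      sum(dsec) - sum(dep)
    w$mol[fl, ] <- S2
  }

  ## 4a. epithelial binding + apoptosis (Eq 2)
  if (length(epi)) {
    w$B_T[epi] <- ap$beta_T * lc_epi$T
    w$B_P[epi] <- ap$beta_P * lc_epi$P
    haz <- prob_epithelial_apoptosis(w$B_T[epi], w$B_P[epi], ap)
    dead <- epi[stats::runif(length(epi)) < haz]
    if (length(dead)) {
      w$alive[dead] <- FALSE
      w$occupancy[cbind(w$ci[dead], w$cj[dead])] <- 0L
      w$counters$epithelial_deaths <- w$counters$epithelial_deaths + length(dead)
    }
  }

  ## 4b. myofibroblast apoptosis, then ECM deposition by survivors
  if (length(myo)) {
    dead <- myo[stats::runif(length(myo)) < ap$p_myo_apop]
    if (length(dead)) {
      w$alive[dead] <- FALSE
      w$occupancy[cbind(w$ci[dead], w$cj[dead])] <- 0L
      w$counters$myofibroblast_deaths <-
        w$counters$myofibroblast_deaths + length(dead)
    }
    surv <- setdiff(myo, dead)
    if (length(surv))
      w$ecm[cbind(w$ci[surv], w$cj[surv])] <-
        w$ecm[cbind(w$ci[surv], w$cj[surv])] + ap$q_ecm
  }

  ## 4c. fibroblast differentiation (Eq 1 with eligibility gate)
  if (length(fib)) {
    sel <- match(fib, fl)
    Tl <- lc_fl$T[sel]; Pl <- lc_fl$P[sel]
    alive_f <- w$alive[fib]
    elig <- alive_f & diff_ratio_ok(Tl, Pl, ap)
    pd <- prob_differentiation(dA[sel], ap) / (1 + ap$k_inhib_diff * Pl)
    conv <- fib[elig & stats::runif(length(fib)) < pd]
    if (length(conv)) {
      w$kind[conv] <- KIND_MYOFIBROBLAST
      w$counters$differentiations <- w$counters$differentiations + length(conv)
    }
  }

  ## 4d. fibroblast division (still-fibroblast survivors)
  if (length(fib)) {
    sel <- match(fib, fl)
    can <- w$alive[fib] & w$kind[fib] == KIND_FIBROBLAST &
      lc_fl$T[sel] >= ap$min_prolifTGFB1 & lc_fl$P[sel] <= ap$max_prolifPGE2
    winners <- fib[can & stats::runif(length(fib)) < prob_division(ap, dt)]
    if (length(winners)) {
      winners <- winners[sample.int(length(winners))]
      w <- grow_world(w, length(winners))
      R0 <- w$config$init$receptors_per_cell
      if (is.na(R0)) R0 <- p$v_R / p$k_tR
      nx <- w$spec$nx; ny <- w$spec$ny
      occ <- w$occupancy; ci <- w$ci; cj <- w$cj
      for (c0 in winners) {
        lin <- pick_empty_neighbor(occ, nx, ny, ci[c0], cj[c0])
        if (lin == 0L) next # contact inhibition
        w$n <- w$n + 1L
        nid <- w$n
        w$kind[nid] <- KIND_FIBROBLAST
        ci[nid] <- (lin - 1L) %% nx + 1L
        cj[nid] <- (lin - 1L) %/% nx + 1L
        w$alive[nid] <- TRUE; w$age[nid] <- 0
        w$mol[nid, ] <- 0; w$mol[nid, 1] <- R0
        occ[lin] <- nid
        w$counters$divisions <- w$counters$divisions + 1
      }
      w$occupancy <- occ; w$ci <- ci; w$cj <- cj
    }
  }

  ## 4e. fibroblast movement
  if (length(fib)) {
    movers <- fib[w$alive[fib] & w$kind[fib] == KIND_FIBROBLAST &
                    stats::runif(length(fib)) < ap$p_move]
    if (length(movers)) {
      movers <- movers[sample.int(length(movers))]
      res <- move_cells_cpp(w$occupancy, w$ci[seq_len(w$n)], w$cj[seq_len(w$n)],
                            movers, w$spec$nx, w$spec$ny)
      w$occupancy <- res$occupancy
      w$ci[seq_len(w$n)] <- res$ci; w$cj[seq_len(w$n)] <- res$cj
    }
  }

  ## 5. activation, latent decay, diffusion + decay
  if (!clampT) {
    frac <- 1 - exp(-w$config$env$k_act_per_min * dt)
    released <- w$latent * frac
    w$latent <- w$latent - released
    w$tgfb[, , 1] <- w$tgfb[, , 1] + released / w$vox_ml
    fdeg <- exp(-halflife_to_rate(w$config$env$halflife_latent_min) * dt)
    w$audit$degraded_latent_ng <- w$audit$degraded_latent_ng +
      sum(w$latent) * (1 - fdeg)
    w$latent <- w$latent * fdeg
    w$tgfb <- diffuse_decay_array(
      w$tgfb, w$spec, w$config$env$D_tgfb1_cm2_s,
      halflife_to_rate(w$config$env$halflife_active_min), dt,
      w$config$run$diffusion_method, w$config$run$n_diff_substeps,
      function(lost) w$audit$degraded_active_ng <<-
        w$audit$degraded_active_ng + lost * w$vox_ml)
  }
  if (!clampP) {
    w$pge2 <- diffuse_decay_array(
      w$pge2, w$spec, w$config$env$D_pge2_cm2_s,
      halflife_to_rate(w$config$env$halflife_pge2_min), dt,
      w$config$run$diffusion_method, w$config$run$n_diff_substeps, NULL)
  }

  w$age[live] <- w$age[live] + dt
  w$time_min <- w$time_min + dt
  w
}

# diffusion + exact decay on a raw array; report_loss receives the decayed
# concentration-sum if non-NULL
diffuse_decay_array <- function(arr, spec, D, k_deg, dt, method, n_sub,
                                report_loss) {
  h <- dt / n_sub
  dx_cm <- spec$dx_um * 1e-4
  alpha <- D * 60 * h / dx_cm^2
  dims <- dim(arr)
  for (s in seq_len(n_sub)) {
    if (alpha > 0) {
      arr <- if (method == "implicit")
        adi_step_cpp(arr, spec$nx, spec$ny, spec$nz, alpha)
      else {
        if (alpha > 1 / 6 + 1e-12)
          stop(sprintf(
            "explicit diffusion unstable: need dt <= %g min per substep",
            dx_cm^2 / (6 * D * 60)), call. = FALSE)
        ftcs_step_cpp(arr, spec$nx, spec$ny, spec$nz, alpha)
      }
      dim(arr) <- dims
    }
    if (k_deg > 0) {
      f <- exp(-k_deg * h)
      if (!is.null(report_loss)) report_loss(sum(arr) * (1 - f))
      arr <- arr * f
    }
  }
  arr
}

record_row <- function(w) {
  live <- which(w$alive[seq_len(w$n)])
  kinds <- w$kind[live]
  flrows <- which(w$kind[seq_len(w$n)] != KIND_EPITHELIAL & w$kind[seq_len(w$n)] != 0L)
  bound_ng <- if (length(flrows))
    sum(w$mol[flrows, 2] + w$mol[flrows, 3]) * TGFB1_NG_PER_MOLECULE else 0
  internal_ng <- if (length(flrows))
    sum(w$mol[flrows, 7]) * TGFB1_NG_PER_MOLECULE else 0
  uptake_ng <- if (length(flrows))
    sum(w$mol[flrows, 6]) * TGFB1_NG_PER_MOLECULE else 0
  c(
    time_h = w$time_min / 60,
    fibroblasts = sum(kinds == KIND_FIBROBLAST),
    myofibroblasts = sum(kinds == KIND_MYOFIBROBLAST),
    epithelial = sum(kinds == KIND_EPITHELIAL),
    active_tgfb1_ng = sum(w$tgfb) * w$vox_ml,
    latent_tgfb1_ng = sum(w$latent),
    pge2_nmol = sum(w$pge2) * w$vox_l,
    ecm = sum(w$ecm),
    cum_divisions = w$counters$divisions,
    cum_differentiations = w$counters$differentiations,
    cum_epithelial_deaths = w$counters$epithelial_deaths,
    cum_myofibroblast_deaths = w$counters$myofibroblast_deaths,
    cum_secreted_latent_ng = w$audit$secreted_latent_ng,
    cum_degraded_latent_ng = w$audit$degraded_latent_ng,
    cum_degraded_active_ng = w$audit$degraded_active_ng,
    cell_bound_tgfb1_ng = bound_ng,
    cum_internal_degraded_ng = internal_ng,
    cum_uptake_ng = uptake_ng
  )
}

#' Run the multi-scale simulation
#'
#' Executes the full time loop for the configured duration. Identical seed
#' and configuration give identical output.
#'
#' @param config A [sim_config()].
#' @param keep_state Keep the final world state in the result (default TRUE;
#'   set FALSE in large batch experiments to save memory).
#' @return A `fibrosim_run` object: list with `timeseries` (a tibble, one
#'   row per record time), `config`, `confluence`, and optionally `state`.
#' @export
#' @examples
#' cfg <- reduced_config(run = list(duration_h = 2, seed = 42))
#' run <- run_simulation(cfg)
#' run$timeseries
run_simulation <- function(config, keep_state = TRUE) {
  set.seed(config$run$seed)
  w <- new_world(config)
  dt <- config$run$dt_abm_min
  n_steps <- ceiling(config$run$duration_h * 60 / dt)
  rec_every <- max(1L, round(config$run$record_every_min / dt))
  rows <- vector("list", n_steps %/% rec_every + 2L)
  rows[[1]] <- record_row(w)
  ri <- 1L
  for (s in seq_len(n_steps)) {
    w <- step_world(w, dt)
    if (s %% rec_every == 0L || s == n_steps) {
      ri <- ri + 1L
      rows[[ri]] <- record_row(w)
    }
  }
  ts <- tibble::as_tibble(do.call(rbind, rows[seq_len(ri)]))
  structure(list(timeseries = ts,
                 config = config, confluence = w$confluence,
                 state = if (keep_state) w else NULL),
            class = "fibrosim_run")
}

#' @export
print.fibrosim_run <- function(x, ...) {
  last <- x$timeseries[nrow(x$timeseries), ]
  cat("<fibrosim_run> ", last$time_h, " h simulated; final counts: ",
      last$fibroblasts, " fibroblasts, ", last$myofibroblasts,
      " myofibroblasts, ", last$epithelial, " epithelial\n", sep = "")
  invisible(x)
}

#' Classify a simulated time series into one of four outcome categories
#'
#' Deterministic rules over the recorded counts, with precedence
#' excessive > rapid > gradual > healthy:
#' \itemize{
#' \item \strong{excessive_proliferation_and_differentiation}: fibroblast
#'   lineage at 168 h at least 4x its initial size and epithelial survival
#'   below 10\%.
#' \item \strong{rapid_epi_death_with_differentiation}: at least 50\%
#'   epithelial loss within the first 24 h.
#' \item \strong{gradual_epi_death_with_proliferation}: epithelial loss
#'   between 25\% and 75\% at 168 h with fibroblasts exceeding 2x initial at
#'   some time.
#' \item \strong{healthy}: epithelial survival at least 90\% and
#'   myofibroblasts below 5\% of the fibroblast lineage at 168 h.
#' }
#' A series matching none of the rules is assigned the nearest category by
#' the same ordered rules, with a warning.
#'
#' @param x A `fibrosim_run` or its `timeseries` tibble (must span >= 168 h).
#' @return A length-1 character: the outcome category.
#' @export
classify_outcome <- function(x) {
  ts <- if (inherits(x, "fibrosim_run")) x$timeseries else x
  if (max(ts$time_h) < 168)
    stop("series too short: outcome classification needs >= 168 h", call. = FALSE)
  epi0 <- ts$epithelial[1]
  fib0 <- max(1, ts$fibroblasts[1])
  at <- function(t) ts[which.min(abs(ts$time_h - t)), ]
  end <- at(168)
  lineage_end <- end$fibroblasts + end$myofibroblasts
  epi_frac_end <- if (epi0 > 0) end$epithelial / epi0 else 1
  epi_frac_24 <- if (epi0 > 0) at(24)$epithelial / epi0 else 1
  fib_peak <- max(ts$fibroblasts[ts$time_h <= 168]) / fib0
  myo_frac_end <- if (lineage_end > 0) end$myofibroblasts / lineage_end else 0

  if (lineage_end >= 4 * fib0 && epi_frac_end < 0.10)
    return("excessive_proliferation_and_differentiation")
  if (epi_frac_24 <= 0.50 && epi0 > 0)
    return("rapid_epi_death_with_differentiation")
  if (epi_frac_end >= 0.25 && epi_frac_end <= 0.75 && fib_peak > 2)
    return("gradual_epi_death_with_proliferation")
  if (epi_frac_end >= 0.90 && myo_frac_end < 0.05)
    return("healthy")
  # nearest category by the same ordered rules
  warning("series matches no category exactly; assigning nearest", call. = FALSE)
  if (epi_frac_end < 0.10 && lineage_end >= 2 * fib0)
    "excessive_proliferation_and_differentiation"
  else if (epi_frac_end < 0.25)
    "rapid_epi_death_with_differentiation"
  else if (epi_frac_end < 0.90)
    "gradual_epi_death_with_proliferation"
  else "healthy"
}

#' Export plain-text snapshots of a finished run
#'
#' Writes three delimited files: per-voxel mediator concentrations, the
#' surface pools, and the cell table.
#'
#' @param run A `fibrosim_run` with `state` kept.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_snapshot <- function(run, dir, prefix = "snapshot") {
  stopifnot(inherits(run, "fibrosim_run"), !is.null(run$state))
  w <- run$state
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- w$spec
  vox <- expand.grid(i = 1:spec$nx, j = 1:spec$ny, k = 1:spec$nz)
  vox$activeTGFB1 <- as.numeric(w$tgfb)
  vox$PGE2 <- as.numeric(w$pge2)
  f1 <- file.path(dir, paste0(prefix, "_voxels.tsv"))
  utils::write.table(vox, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  surf <- expand.grid(i = 1:spec$nx, j = 1:spec$ny)
  surf$ecm <- as.numeric(w$ecm)
  surf$latentTGFB1 <- as.numeric(w$latent)
  f2 <- file.path(dir, paste0(prefix, "_surface.tsv"))
  utils::write.table(surf, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  n <- w$n
  cells <- data.frame(id = seq_len(n), kind = KIND_LEVELS[w$kind[seq_len(n)]],
                      i = w$ci[seq_len(n)], j = w$cj[seq_len(n)],
                      alive = w$alive[seq_len(n)],
                      A_cum = w$mol[seq_len(n), 5],
                      B_T = w$B_T[seq_len(n)], B_P = w$B_P[seq_len(n)])
  f3 <- file.path(dir, paste0(prefix, "_cells.tsv"))
  utils::write.table(cells, f3, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2, f3))
}
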