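## Intracellular TGF-beta1 receptor trafficking model run inside every
## fibroblast and myofibroblast agent: receptor synthesis, ligand binding and
## dissociation, internalization, recycling, degradation, a coarse-grained
## SMAD signal, PGE2 inhibition, alpha-SMA synthesis and latent TGF-beta1
## production.

#' Kinetic constants of the per-cell receptor/alpha-SMA ODE system
#'
#' Signalling is coarse-grained: internalized ligand-receptor complexes drive
#' a saturating signal `S = C_i / (C_i + K_S)`, and local PGE2 acts as a
#' multiplicative inhibitor `I_P = 1 / (1 + P / K_P)` on both alpha-SMA and
#' latent TGF-beta1 synthesis. alpha-SMA synthesis saturates as the cell
#' approaches its synthesis capacity `a_max`.
#'
#' @param v_R Receptor synthesis rate, receptors/cell/min.
#' @param k_on Association rate for fibroblasts, (ng/ml)^-1 min^-1.
#' @param k_onM Association rate for myofibroblasts, same units.
#' @param k_off Complex dissociation rate, 1/min.
#' @param k_int Surface-complex internalization rate, 1/min.
#' @param k_rec Recycling rate of internalized complexes, 1/min.
#' @param k_degC Internalized-complex degradation rate, 1/min.
#' @param k_tR Constitutive free-receptor turnover, 1/min.
#' @param K_S Signal half-saturation, internalized complexes/cell.
#' @param K_P PGE2 inhibition constant, nM.
#' @param k_synA Maximal alpha-SMA synthesis rate, a.u./min.
#' @param k_degA alpha-SMA decay rate, 1/min.
#' @param k_synL Maximal latent TGF-beta1 synthesis rate, ng/cell/min.
#' @param b0 Basal fraction of latent synthesis without signal, in [0, 1].
#' @param a_max alpha-SMA synthesis capacity, a.u. (shared with Eq 1).
#' @return A `molecular_params` object.
#' @export
molecular_params <- function(v_R = 100, k_on = 0.01, k_onM = 0.001,
                             k_off = 0.24, k_int = 0.2, k_rec = 0.001,
                             k_degC = 0.005, k_tR = 0.01, K_S = 200,
                             K_P = 20, k_synA = 1, k_degA = 0.01,
                             k_synL = 1.3e-6, b0 = 0.2, a_max = 10) {
  p <- list(v_R = v_R, k_on = k_on, k_onM = k_onM, k_off = k_off,
            k_int = k_int, k_rec = k_rec, k_degC = k_degC, k_tR = k_tR,
            K_S = K_S, K_P = K_P, k_synA = k_synA, k_degA = k_degA,
            k_synL = k_synL, b0 = b0, a_max = a_max)
  rates <- unlist(p[c("v_R", "k_on", "k_onM", "k_off", "k_int", "k_rec",
                      "k_degC", "k_tR", "k_synA", "k_degA", "k_synL")])
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (p$K_S <= 0 || p$K_P <= 0) stop("K_S and K_P must be > 0", call. = FALSE)
  if (p$b0 < 0 || p$b0 > 1) stop("b0 must lie in [0, 1]", call. = FALSE)
  if (p$a_max <= 0) stop("a_max must be > 0", call. = FALSE)
  structure(p, class = "molecular_params")
}

#' Intracellular state of a fibroblast-lineage cell
#'
#' @param R Free surface receptor complexes per cell (default: the
#'   ligand-free steady state `v_R / k_tR`).
#' @param C_s Surface ligand-receptor complexes per cell.
#' @param C_i Internalized complexes per cell.
#' @param A Current intracellular alpha-SMA, a.u.
#' @param A_cum Cumulative alpha-SMA synthesized, a.u. (nondecreasing).
#' @param p A [molecular_params()] used for the default `R`.
#' @return A named numeric vector of class `molecular_state`.
#' @export
molecular_state <- function(R = NULL, C_s = 0, C_i = 0, A = 0, A_cum = 0,
                            p = molecular_params()) {
  if (is.null(R)) R <- p$v_R / p$k_tR
  s <- c(R = R, C_s = C_s, C_i = C_i, A = A, A_cum = A_cum)
  if (any(s < 0)) stop("molecular state must be nonnegative", call. = FALSE)
  if (A > A_cum + 1e-9) stop("A cannot exceed A_cum", call. = FALSE)
  structure(s, class = "molecular_state")
}

## ---- vectorised core --------------------------------------------------
## State matrix columns (one row per cell):
## 1 R, 2 C_s, 3 C_i, 4 A, 5 A_cum,
## 6 U      cumulative net ligand uptake, molecules
## 7 Ldeg   cumulative internally degraded ligand, molecules
## 8 Lsec   cumulative latent TGF-beta1 secreted, ng
## 9 T      local active TGF-beta1, ng/ml (evolves only when depleting)
MOL_NSTATE <- 9L

mol_state_matrix <- function(n, p) {
  m <- matrix(0, n, MOL_NSTATE)
  m[, 1] <- p$v_R / p$k_tR
  m
}

# Time-derivative of the full per-cell system, vectorised over cells.
# kon is a per-cell vector (k_on or k_onM); P a per-cell vector (frozen);
# omega converts molecules to ng/ml in the cell's voxel (0 = no depletion).
mol_deriv_mat <- function(S, P, kon, p, omega) {
  Tl <- S[, 9]
  bind <- kon * Tl * S[, 1]
  diss <- p$k_off * S[, 2]
  Ssig <- S[, 3] / (S[, 3] + p$K_S)
  I_P <- 1 / (1 + P / p$K_P)
  synA <- p$k_synA * Ssig * I_P * pmax(0, 1 - S[, 4] / p$a_max)
  d <- matrix(0, nrow(S), MOL_NSTATE)
  d[, 1] <- p$v_R + p$k_rec * S[, 3] - bind + diss - p$k_tR * S[, 1]
  d[, 2] <- bind - diss - p$k_int * S[, 2]
  d[, 3] <- p$k_int * S[, 2] - (p$k_rec + p$k_degC) * S[, 3]
  d[, 4] <- synA - p$k_degA * S[, 4]
  d[, 5] <- synA
  d[, 6] <- bind - diss
  d[, 7] <- (p$k_rec + p$k_degC) * S[, 3]
  d[, 8] <- p$k_synL * (p$b0 + (1 - p$b0) * Ssig) * I_P
  d[, 9] <- -(bind - diss) * omega
  d
}

# Classic RK4 with fixed substeps, batched over cells (compiled kernel).
# The local-T column and the uptake counter integrate the same flux with the
# same weights, so the joint cell+voxel TGF-beta1 mass balance is
# machine-exact.
mol_rk4 <- function(S, P, kon, p, dt_min, n_sub, omega) {
  par <- c(p$v_R, p$k_off, p$k_int, p$k_rec, p$k_degC, p$k_tR, p$K_S, p$K_P,
           p$k_synA, p$k_degA, p$k_synL, p$b0, p$a_max)
  if (length(P) == 1L) P <- rep(P, nrow(S))
  if (length(kon) == 1L) kon <- rep(kon, nrow(S))
  mol_rk4_cpp(S, P, kon, par, dt_min, as.integer(n_sub), omega)
}

# substep count guaranteeing RK4 stability for the fastest local rate
mol_substeps <- function(p, dt_min, n_min = 6L) {
  lam <- max(p$k_off + p$k_int, p$k_rec + p$k_degC, p$k_tR, p$k_degA)
  max(n_min, ceiling(dt_min * lam / 1.5))
}

## ---- spec-facing scalar operations ------------------------------------

#' Time-derivatives of the intracellular system
#'
#' @param state A [molecular_state()].
#' @param T_local Local active TGF-beta1, ng/ml.
#' @param P_local Local PGE2, nM.
#' @param p A [molecular_params()].
#' @param myofibroblast If `TRUE` the myofibroblast association rate `k_onM`
#'   is used in place of `k_on`.
#' @return A list: `dstate` (named derivatives), `ligand_uptake_flux_ng_min`
#'   (net binding flux as ng/cell/min) and `latent_secretion_flux_ng_min`.
#' @export
molecular_derivatives <- function(state, T_local, P_local, p = molecular_params(),
                                  myofibroblast = FALSE) {
  if (T_local < 0 || P_local < 0 || any(unclass(state) < 0))
    stop("state and local concentrations must be nonnegative", call. = FALSE)
  S <- matrix(0, 1, MOL_NSTATE)
  S[1, 1:5] <- unclass(state)[1:5]
  S[1, 9] <- T_local
  kon <- if (myofibroblast) p$k_onM else p$k_on
  d <- mol_deriv_mat(S, P_local, kon, p, omega = 0)
  list(
    dstate = c(R = d[1, 1], C_s = d[1, 2], C_i = d[1, 3], A = d[1, 4],
               A_cum = d[1, 5]),
    ligand_uptake_flux_ng_min = d[1, 6] * TGFB1_NG_PER_MOLECULE,
    latent_secretion_flux_ng_min = d[1, 8]
  )
}

#' Integrate the intracellular system over one ABM step
#'
#' Local concentrations are held frozen by default; with
#' `voxel_volume_ml` supplied, the cell's voxel is depleted/replenished by
#' net binding as an extra coupled ODE (the engine's mode).
#'
#' @inheritParams molecular_derivatives
#' @param dt_min Step length in minutes.
#' @param n_sub Number of RK4 substeps (default chosen from the fastest rate).
#' @param voxel_volume_ml If non-`NULL`, couple local depletion.
#' @return List: updated `state`, `uptake_ng`, `secretion_ng`,
#'   `internal_degraded_ng`, and final `T_local`.
#' @export
integrate_molecular <- function(state, T_local, P_local, p = molecular_params(),
                                dt_min = 10, myofibroblast = FALSE,
                                n_sub = NULL, voxel_volume_ml = NULL) {
  stopifnot(dt_min > 0)
  if (is.null(n_sub)) n_sub <- mol_substeps(p, dt_min)
  S <- matrix(0, 1, MOL_NSTATE)
  S[1, 1:5] <- unclass(state)[1:5]
  S[1, 9] <- T_local
  omega <- if (is.null(voxel_volume_ml)) 0 else
    TGFB1_NG_PER_MOLECULE / voxel_volume_ml
  kon <- if (myofibroblast) p$k_onM else p$k_on
  S2 <- mol_rk4(S, P_local, kon, p, dt_min, n_sub, omega)
  if (any(!is.finite(S2)))
    stop("molecular integration failed (non-finite state); state was: ",
         paste(signif(S[1, 1:5], 4), collapse = ", "), call. = FALSE)
  out_state <- molecular_state(R = S2[1, 1], C_s = S2[1, 2], C_i = S2[1, 3],
                               A = S2[1, 4], A_cum = S2[1, 5], p = p)
  list(state = out_state,
       uptake_ng = S2[1, 6] * TGFB1_NG_PER_MOLECULE,
       secretion_ng = S2[1, 8],
       internal_degraded_ng = S2[1, 7] * TGFB1_NG_PER_MOLECULE,
       T_local = if (is.null(voxel_volume_ml)) T_local else S2[1, 9])
}

#' Steady-state fraction of receptors in surface complexes
#'
#' Closed form for the linear R / C_s / C_i subsystem at fixed ligand
#' concentration; used for initialization and as a test oracle.
#'
#' @inheritParams molecular_derivatives
#' @return Fraction `C_s / (R + C_s + C_i)` at steady state.
#' @export
equilibrium_bound_fraction <- function(T_local, p = molecular_params(),
                                       myofibroblast = FALSE) {
  stopifnot(T_local >= 0)
  kon <- if (myofibroblast) p$k_onM else p$k_on
  a <- kon * T_local
  if (a == 0) return(0)
  # C_s = cR * R, C_i = ci * R at steady state
  cR <- a / (p$k_off + p$k_int)
  ci <- p$k_int * cR / (p$k_rec + p$k_degC)
  cR / (1 + cR + ci)
}
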