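## Cell agents and their per-step rules: fibroblast movement, proliferation
## and differentiation, epithelial coarse-grained mediator binding and
## apoptosis, myofibroblast apoptosis and ECM / latent TGF-beta1 deposition.

# cell kind codes used throughout the engine
KIND_FIBROBLAST <- 1L
KIND_MYOFIBROBLAST <- 2L
KIND_EPITHELIAL <- 3L
KIND_LEVELS <- c("fibroblast", "myofibroblast", "epithelial")

#' Cellular-scale rule parameters
#'
#' @param p_move Probability a fibroblast attempts a move per ABM step.
#' @param T_double_h Fibroblast doubling time, hours.
#' @param min_prolifTGFB1 Minimum local active TGF-beta1 permitting
#'   proliferation, ng/ml.
#' @param max_prolifPGE2 Maximum local PGE2 permitting proliferation, nM.
#'   Default 3 nM: the in vitro data bound the threshold to the open
#'   interval (1, 10] nM, and 3 nM is its logarithmic midpoint.
#' @param slope Differentiation-rule sensitivity (Eq 1), dimensionless.
#' @param a_max Maximum alpha-SMA a cell can synthesize, a.u.
#' @param ratio_diff Minimum local TGF-beta1 : PGE2 ratio permitting
#'   differentiation (dimensionless, on `T / (ratio_scale * P + ratio_eps)`).
#' @param ratio_scale PGE2 weight in the differentiation ratio, (ng/ml)/nM.
#' @param ratio_eps Regularizing floor of the ratio denominator, ng/ml.
#' @param k_inhib_diff Strength of PGE2 inhibition of differentiation, 1/nM.
#' @param m Epithelial apoptosis sensitivity to bound TGF-beta1 (Eq 2),
#'   per-step hazard scale.
#' @param k Weight of bound PGE2 in the Eq 2 denominator, dimensionless.
#' @param C Basal per-step apoptosis hazard (Eq 2 intercept).
#' @param beta_T Epithelial TGF-beta1 binding coefficient (quasi-equilibrium).
#' @param beta_P Epithelial PGE2 binding coefficient (quasi-equilibrium).
#' @param V_ePGE2 Epithelial PGE2 synthesis rate, nmol/cell/min.
#' @param eps_fibPGE2 Fibroblast PGE2 synthesis as a fraction of `V_ePGE2`.
#' @param eps_epiTGFB1 Epithelial latent TGF-beta1 synthesis as a fraction of
#'   the fibroblast maximal rate `k_synL`.
#' @param p_myo_apop Myofibroblast apoptosis probability per step.
#' @param q_ecm ECM deposited per myofibroblast per step, a.u.
#' @param f_lat_surface Fraction of secreted latent TGF-beta1 deposited to
#'   the surface pool.
#' @return An `agent_params` object.
#' @export
agent_params <- function(p_move = 0.5, T_double_h = 24,
                         min_prolifTGFB1 = 0, max_prolifPGE2 = 3,
                         slope = 0.8, a_max = 10,
                         ratio_diff = 30, ratio_scale = 0.02, ratio_eps = 0.05,
                         k_inhib_diff = 0.02,
                         m = 0.2, k = 100, C = 1e-7,
                         beta_T = 1, beta_P = 1,
                         V_ePGE2 = 3e-11, eps_fibPGE2 = 0.01,
                         eps_epiTGFB1 = 0.01,
                         p_myo_apop = 3e-4, q_ecm = 1, f_lat_surface = 1) {
  ap <- as.list(environment())
  probs <- unlist(ap[c("p_move", "p_myo_apop", "f_lat_surface")])
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(unlist(ap) < 0)) stop("rates and thresholds must be >= 0", call. = FALSE)
  if (a_max <= 0) stop("a_max must be > 0", call. = FALSE)
  structure(ap, class = "agent_params")
}

#' Per-step fibroblast differentiation probability (Eq 1)
#'
#' The probability is proportional to the alpha-SMA the cell synthesized
#' since its last differentiation check, normalized by the synthesis
#' capacity, and clamped to [0, 1].
#'
#' @param A_cum_step alpha-SMA synthesized over the step, a.u.
#' @param ap An [agent_params()].
#' @return Probability in [0, 1].
#' @export
prob_differentiation <- function(A_cum_step, ap = agent_params()) {
  if (ap$a_max == 0) stop("a_max must be > 0", call. = FALSE)
  stopifnot(all(A_cum_step >= 0))
  pmin(1, pmax(0, ap$slope * A_cum_step / ap$a_max))
}

#' Per-step epithelial apoptosis probability (Eq 2)
#'
#' `m * B_T / (B_T + k * B_P) + C`, clamped to [0, 1]; the fraction is
#' defined as 0 when both bound amounts are 0.
#'
#' @param B_T Bound TGF-beta1, ng-equivalents.
#' @param B_P Bound PGE2, nM-equivalents.
#' @param ap An [agent_params()].
#' @return Probability in [0, 1].
#' @export
prob_epithelial_apoptosis <- function(B_T, B_P, ap = agent_params()) {
  stopifnot(all(B_T >= 0), all(B_P >= 0))
  den <- B_T + ap$k * B_P
  frac <- ifelse(den > 0, B_T / den, 0)
  pmin(1, pmax(0, ap$m * frac + ap$C))
}

#' Quasi-equilibrium epithelial mediator binding
#'
#' Epithelial binding is coarse-grained as a linear quasi-equilibrium with
#' the local concentrations: `B_T = beta_T * T`, `B_P = beta_P * P`.
#'
#' @param cell A cell list with `kind == "epithelial"`.
#' @param T_local Local active TGF-beta1, ng/ml.
#' @param P_local Local PGE2, nM.
#' @param ap An [agent_params()].
#' @return The cell with updated `B_T` and `B_P`.
#' @export
epithelial_binding_update <- function(cell, T_local, P_local,
                                      ap = agent_params()) {
  if (!identical(cell$kind, "epithelial"))
    stop("binding update applies to epithelial cells only", call. = FALSE)
  cell$B_T <- ap$beta_T * T_local
  cell$B_P <- ap$beta_P * P_local
  cell
}

#' Attempt a fibroblast move
#'
#' With probability `p_move` the cell picks a uniformly random empty Moore
#' neighbour and relocates; if every neighbour is occupied it stays put.
#'
#' @param cell A cell list with fields `i`, `j`.
#' @param spec A [grid_spec()].
#' @param occupancy Integer matrix (`nx x ny`), 0 for empty voxels.
#' @param ap An [agent_params()].
#' @return List with the (possibly moved) `cell` and updated `occupancy`.
#' @export
attempt_move <- function(cell, spec, occupancy, ap = agent_params()) {
  if (stats::runif(1) < ap$p_move) {
    nb <- surface_neighbors(spec, cell$i, cell$j)
    empty <- nb[occupancy[nb] == 0L, , drop = FALSE]
    if (nrow(empty) > 0) {
      pick <- empty[sample.int(nrow(empty), 1L), ]
      occupancy[cell$i, cell$j] <- 0L
      cell$i <- pick[["i"]]; cell$j <- pick[["j"]]
      occupancy[cell$i, cell$j] <- cell$id
    }
  }
  list(cell = cell, occupancy = occupancy)
}

# per-step division probability at step length dt
prob_division <- function(ap, dt_min) dt_min * log(2) / (ap$T_double_h * 60)

#' Attempt fibroblast division
#'
#' Division requires local TGF-beta1 at or above `min_prolifTGFB1`, local
#' PGE2 at or below `max_prolifPGE2`, and an empty Moore neighbour (contact
#' inhibition); given permission, the cell divides with probability
#' `dt * ln 2 / T_double` and the daughter (fresh molecular state) is placed
#' in a uniformly chosen empty neighbour.
#'
#' @inheritParams attempt_move
#' @param T_local,P_local Local mediator concentrations.
#' @param dt_min ABM step length, minutes.
#' @return List with `daughter` (a cell list or `NULL`) and `occupancy`.
#' @export
attempt_proliferation <- function(cell, T_local, P_local, spec, occupancy,
                                  ap = agent_params(), dt_min = 10) {
  if (T_local < ap$min_prolifTGFB1 || P_local > ap$max_prolifPGE2)
    return(list(daughter = NULL, occupancy = occupancy))
  nb <- surface_neighbors(spec, cell$i, cell$j)
  empty <- nb[occupancy[nb] == 0L, , drop = FALSE]
  if (nrow(empty) == 0 || stats::runif(1) >= prob_division(ap, dt_min))
    return(list(daughter = NULL, occupancy = occupancy))
  pick <- empty[sample.int(nrow(empty), 1L), ]
  daughter <- list(id = NA_integer_, kind = "fibroblast",
                   i = pick[["i"]], j = pick[["j"]], alive = TRUE, age = 0)
  list(daughter = daughter, occupancy = occupancy)
}

# eligibility gate of the differentiation rule
diff_ratio_ok <- function(T_local, P_local, ap) {
  T_local / (ap$ratio_scale * P_local + ap$ratio_eps) >= ap$ratio_diff
}

#' Fibroblast-to-myofibroblast differentiation check
#'
#' Eligible only when the local TGF-beta1 : PGE2 ratio clears
#' `ratio_diff`; then converts with probability
#' `prob_differentiation(A_cum_step) / (1 + k_inhib_diff * P_local)`.
#' Conversion is permanent: the myofibroblast neither moves nor divides and
#' its molecular model continues with the `k_onM` association rate.
#'
#' @param cell A fibroblast cell list.
#' @param A_cum_step alpha-SMA synthesized over the step, a.u.
#' @param T_local,P_local Local mediator concentrations.
#' @param ap An [agent_params()].
#' @return The cell, with `kind` possibly switched to `"myofibroblast"`.
#' @export
maybe_differentiate <- function(cell, A_cum_step, T_local, P_local,
                                ap = agent_params()) {
  if (!diff_ratio_ok(T_local, P_local, ap)) return(cell)
  p <- prob_differentiation(A_cum_step, ap) / (1 + ap$k_inhib_diff * P_local)
  if (stats::runif(1) < p) cell$kind <- "myofibroblast"
  cell
}

#' One myofibroblast step: apoptosis draw, then deposition
#'
#' @param cell A myofibroblast cell list.
#' @param pools A [surface_pools()].
#' @param latent_secretion_ng Latent TGF-beta1 the cell secreted this step.
#' @param ap An [agent_params()].
#' @return List with `cell` (its `alive` flag possibly cleared) and `pools`.
#' @export
myofibroblast_step <- function(cell, pools, latent_secretion_ng = 0,
                               ap = agent_params()) {
  if (stats::runif(1) < ap$p_myo_apop) {
    cell$alive <- FALSE
    return(list(cell = cell, pools = pools))
  }
  pools <- deposit_to_surface(pools, cell$i, cell$j, ecm_amount = ap$q_ecm,
                              latent_amount = ap$f_lat_surface * latent_secretion_ng)
  list(cell = cell, pools = pools)
}
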