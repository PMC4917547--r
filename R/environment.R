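## The simulated culture well: voxel lattice, soluble mediator fields with
## diffusion + first-order decay, and the immobilized surface pools (ECM,
## latent TGF-beta1) on the plate bottom.

# TGF-beta1 homodimer, ~25 kDa; used to interconvert molecules and ng
TGFB1_NG_PER_MOLECULE <- 25000 / 6.02214076e23 * 1e9

#' Define the voxel lattice of the simulated culture well
#'
#' The default geometry is an 81 x 81 grid of 22-um voxels with 282 layers:
#' layer 1 is the plate surface where cells, ECM and latent TGF-beta1 sit,
#' the layers above are the media compartment.
#'
#' @param nx,ny Compartments per side of each layer.
#' @param nz Number of layers (plate surface plus media).
#' @param dx_um Voxel edge length in micrometres.
#' @return A `grid_spec` object (a named list).
#' @export
#' @examples
#' spec <- grid_spec()
#' total_compartments(spec)
#' total_volume_ul(spec)
grid_spec <- function(nx = 81L, ny = 81L, nz = 282L, dx_um = 22) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 1L) || any(is.na(c(nx, ny, nz))))
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.finite(dx_um) || dx_um <= 0)
    stop("voxel edge length dx_um must be > 0", call. = FALSE)
  structure(list(nx = nx, ny = ny, nz = nz, dx_um = dx_um),
            class = "grid_spec")
}

#' Total number of lattice compartments
#' @param spec A [grid_spec()].
#' @return Integer-valued count `nx * ny * nz`.
#' @export
total_compartments <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  as.numeric(spec$nx) * spec$ny * spec$nz
}

#' Compartments in a single layer
#' @param spec A [grid_spec()].
#' @export
compartments_per_layer <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  as.numeric(spec$nx) * spec$ny
}

#' Total simulated volume in microlitres
#' @param spec A [grid_spec()].
#' @export
total_volume_ul <- function(spec) {
  # 1 uL = 1e9 um^3
  total_compartments(spec) * spec$dx_um^3 / 1e9
}

# voxel volume in ml (1 um^3 = 1e-12 ml)
voxel_volume_ml <- function(spec) spec$dx_um^3 * 1e-12

# voxel volume in litres
voxel_volume_l <- function(spec) spec$dx_um^3 * 1e-15

#' Moore neighbourhood of a plate-surface voxel
#'
#' @param spec A [grid_spec()].
#' @param i,j 1-based surface voxel indices.
#' @return A two-column matrix (i, j) of the in-bounds neighbours (up to 8);
#'   boundaries truncate, self excluded.
#' @export
surface_neighbors <- function(spec, i, j) {
  stopifnot(inherits(spec, "grid_spec"))
  if (i < 1 || i > spec$nx || j < 1 || j > spec$ny)
    stop("surface index (", i, ", ", j, ") out of range", call. = FALSE)
  di <- rep(-1:1, times = 3)
  dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= spec$nx & jj >= 1 & jj <= spec$ny
  cbind(i = ii[ok], j = jj[ok])
}

#' Convert a first-order half-life to a rate constant
#' @param t_half Half-life in minutes.
#' @return Rate constant `ln(2) / t_half` in 1/min.
#' @export
halflife_to_rate <- function(t_half) {
  if (any(!is.finite(t_half) & !is.infinite(t_half)) || any(t_half <= 0))
    stop("half-life must be > 0", call. = FALSE)
  log(2) / t_half
}

#' Create a soluble mediator field
#'
#' @param spec A [grid_spec()].
#' @param name Mediator name, `"activeTGFB1"` (ng/ml) or `"PGE2"` (nM).
#' @param conc Initial concentration: a scalar (uniform) or an
#'   `nx x ny x nz` array.
#' @param D_cm2_s Diffusivity in cm^2/s.
#' @param k_deg_per_min First-order decay rate in 1/min.
#' @return A `mediator_field` object.
#' @export
mediator_field <- function(spec, name = c("activeTGFB1", "PGE2"), conc = 0,
                           D_cm2_s = 2e-7, k_deg_per_min = 0) {
  name <- match.arg(name)
  stopifnot(inherits(spec, "grid_spec"))
  if (length(conc) == 1L) conc <- array(conc, dim = c(spec$nx, spec$ny, spec$nz))
  stopifnot(identical(dim(conc), c(spec$nx, spec$ny, spec$nz)))
  if (any(conc < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  structure(list(name = name, conc = conc, D_cm2_s = D_cm2_s,
                 k_deg_per_min = k_deg_per_min, spec = spec),
            class = "mediator_field")
}

# stability bound of the explicit scheme, in minutes
ftcs_max_dt_min <- function(field) {
  dx_cm <- field$spec$dx_um * 1e-4
  D_min <- field$D_cm2_s * 60
  if (D_min <= 0) return(Inf)
  dx_cm^2 / (6 * D_min)
}

#' Advance a mediator field by one diffusion + decay update
#'
#' Diffusion uses either the explicit 7-point FTCS stencil (subject to the
#' stability bound `dt <= dx^2 / (6 D)`) or an unconditionally stable
#' implicit dimensional-split backward-Euler scheme. Decay is applied as the
#' exact factor `exp(-k_deg * dt)`. Boundaries are reflecting on all six
#' faces (closed culture well): with decay off, total mass is conserved.
#'
#' @param field A [mediator_field()].
#' @param dt_min Time step in minutes.
#' @param method `"ftcs"` (explicit) or `"implicit"`.
#' @return The updated `mediator_field`.
#' @export
diffusion_decay_step <- function(field, dt_min, method = c("ftcs", "implicit")) {
  method <- match.arg(method)
  stopifnot(inherits(field, "mediator_field"), dt_min > 0)
  spec <- field$spec
  dx_cm <- spec$dx_um * 1e-4
  alpha <- field$D_cm2_s * 60 * dt_min / dx_cm^2
  if (alpha > 0) {
    if (method == "ftcs") {
      if (alpha > 1 / 6 + 1e-12)
        stop(sprintf(
          "explicit scheme unstable at dt = %g min; maximum stable dt is %g min",
          dt_min, ftcs_max_dt_min(field)), call. = FALSE)
      new <- ftcs_step_cpp(as.numeric(field$conc), spec$nx, spec$ny, spec$nz,
                           alpha)
    } else {
      new <- adi_step_cpp(as.numeric(field$conc), spec$nx, spec$ny, spec$nz,
                          alpha)
    }
    field$conc <- array(new, dim = dim(field$conc))
  }
  if (field$k_deg_per_min > 0)
    field$conc <- field$conc * exp(-field$k_deg_per_min * dt_min)
  field$conc[field$conc < 0] <- 0 # guard against rounding
  field
}

#' Total mediator mass in a field
#'
#' @param field A [mediator_field()].
#' @return Mass in ng (TGF-beta1 fields, ng/ml concentration) or nmol (PGE2
#'   fields, nM concentration).
#' @export
field_total_mass <- function(field) {
  if (field$name == "activeTGFB1")
    sum(field$conc) * voxel_volume_ml(field$spec)
  else
    sum(field$conc) * voxel_volume_l(field$spec)
}

#' Immobilized surface pools on the plate bottom
#'
#' ECM (arbitrary mass units) and latent TGF-beta1 (ng) per surface voxel.
#' Latent TGF-beta1 adheres to the matrix; activation releases active
#' mediator into the overlying field. Neither pool is transported laterally.
#'
#' @param spec A [grid_spec()].
#' @param k_act_per_min Latent-to-active activation rate, 1/min.
#' @param k_degL_per_min Latent decay rate, 1/min.
#' @return A `surface_pools` object.
#' @export
surface_pools <- function(spec, k_act_per_min = 0.01,
                          k_degL_per_min = halflife_to_rate(9.2)) {
  stopifnot(inherits(spec, "grid_spec"))
  z <- matrix(0, spec$nx, spec$ny)
  structure(list(ecm = z, latentTGFB1 = z, k_act_per_min = k_act_per_min,
                 k_degL_per_min = k_degL_per_min, spec = spec),
            class = "surface_pools")
}

#' Release active TGF-beta1 from the latent surface pool
#'
#' Each surface voxel loses latent mass `L * (1 - exp(-k_act * dt))`; the
#' same mass appears as active concentration in the voxel directly above the
#' matrix. Total TGF-beta1 mass is conserved across the transfer.
#'
#' @param pools A [surface_pools()].
#' @param active The active TGF-beta1 [mediator_field()].
#' @param dt_min Time step in minutes.
#' @return List with updated `pools` and `active` and the total `transferred`
#'   mass (ng).
#' @export
activate_latent <- function(pools, active, dt_min) {
  stopifnot(inherits(pools, "surface_pools"), inherits(active, "mediator_field"),
            dt_min > 0)
  frac <- 1 - exp(-pools$k_act_per_min * dt_min)
  released <- pools$latentTGFB1 * frac
  pools$latentTGFB1 <- pools$latentTGFB1 - released
  active$conc[, , 1] <- active$conc[, , 1] + released / voxel_volume_ml(pools$spec)
  list(pools = pools, active = active, transferred = sum(released))
}

#' Deposit ECM and latent TGF-beta1 onto a surface voxel
#'
#' @param pools A [surface_pools()].
#' @param i,j Surface voxel indices.
#' @param ecm_amount ECM mass to add (arbitrary units).
#' @param latent_amount Latent TGF-beta1 to add (ng).
#' @return Updated `surface_pools`.
#' @export
deposit_to_surface <- function(pools, i, j, ecm_amount = 0, latent_amount = 0) {
  stopifnot(inherits(pools, "surface_pools"))
  if (ecm_amount < 0 || latent_amount < 0)
    stop("deposited amounts must be nonnegative", call. = FALSE)
  pools$ecm[i, j] <- pools$ecm[i, j] + ecm_amount
  pools$latentTGFB1[i, j] <- pools$latentTGFB1[i, j] + latent_amount
  pools
}

# exact latent decay over dt; returns pools and the mass lost
decay_latent <- function(pools, dt_min) {
  f <- exp(-pools$k_degL_per_min * dt_min)
  lost <- sum(pools$latentTGFB1) * (1 - f)
  pools$latentTGFB1 <- pools$latentTGFB1 * f
  list(pools = pools, degraded = lost)
}
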