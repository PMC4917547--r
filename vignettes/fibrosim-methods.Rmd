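---
title: "fibrosim: model, calibration and experiment design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibrosim: model, calibration and experiment design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrosim)
```

fibrosim simulates an in vitro co-culture of lung fibroblasts and alveolar
epithelial cells as a hybrid multi-scale model: a stochastic cellular-scale
agent model on the bottom of a virtual culture well, a molecular-scale ODE
system inside every fibroblast-lineage cell, and two diffusible mediators —
active TGF-β1 (pro-fibrotic) and PGE~2~ (anti-fibrotic) — coupling the two
scales through the shared 3D medium. The purpose is to study how the mutual
regulation of fibroblasts and epithelium partitions outcomes between healthy
repair and fibrosis, and to screen single versus combined ("two-hit")
virtual interventions.

## The simulated well

The default lattice is 81 × 81 voxels per layer and 282 layers of 22 µm
voxels: 6561 surface sites, 1,850,202 compartments, ≈19.7 µL of medium about
6.2 mm deep. Layer 1 is the plate surface; cells, cross-linked ECM and
matrix-bound latent TGF-β1 live only there. 5000 epithelial cells and 500
fibroblasts seeded at random occupy ≈84 % of the surface.

Soluble mediators diffuse in 3D with first-order decay. Active TGF-β1
decays with a 2.7 min half-life and latent TGF-β1 with 9.2 min,
first-order, following the published clearance measurements; PGE~2~ decay is
not published for this system and is set to a 6 h half-life, a typical
culture-medium stability scale. Diffusivities (TGF-β1 2×10⁻⁷ cm²/s, PGE~2~
5×10⁻⁶ cm²/s) are order-of-magnitude literature values for a 25 kDa protein
versus a small lipid; neither is varied in the sensitivity analysis.

Two transport schemes are implemented. The explicit 7-point FTCS stencil is
kept because it can be verified exactly against a dense Laplacian and
against the analytic heat kernel; its stability bound
(`dt ≤ dx²/6D`, about 0.16 s for PGE~2~) would require ~3700 substeps per
10-minute ABM step, so the engine's default is an implicit dimensional-split
backward-Euler solve (Thomas algorithm per lattice line). The implicit
scheme is unconditionally stable, conserves mass to ~10⁻¹² per step under
the same no-flux boundaries, and cannot produce negative concentrations; it
passes the same conservation oracle as the explicit scheme. All six faces
are reflecting — a closed well with no medium changes.

## Molecular scale

Each fibroblast and myofibroblast carries a receptor-trafficking system:
free surface receptors `R` (synthesis `v_R`, turnover `k_tR`), surface
complexes `C_s` (binding `k_on·T`, dissociation `k_off`, internalization
`k_int`), internalized complexes `C_i` (recycling `k_rec`, degradation
`k_degC`). Downstream signalling is coarse-grained into
`S = C_i/(C_i + K_S)` and PGE~2~ inhibition into `I_P = 1/(1 + P/K_P)`,
which multiplies both α-SMA synthesis and latent TGF-β1 production:

* `dA/dt = k_synA · S · I_P · (1 − A/a_max) − k_degA · A`
* `dA_cum/dt = k_synA · S · I_P · (1 − A/a_max)`
* latent secretion `= k_synL · (b0 + (1 − b0)·S) · I_P`

The capacity factor `(1 − A/a_max)` makes "the maximum amount of α-SMA a
cell can synthesize" an actual saturation level of the state variable.
Without it, the differentiation rule depends on `slope` and `a_max` only
through their ratio and `a_max` cannot be recovered by calibration; with
it, dose responses that push cells near the cap identify both constants.

Defaults are standard receptor-trafficking magnitudes: `v_R = 100` /min and
`k_tR = 0.01` /min (ligand-free steady state 10⁴ receptors/cell),
`k_off = 0.24` /min, `k_int = 0.2` /min. Internalized-complex clearance is
slow (`k_rec + k_degC = 0.006` /min, ≈2.8 h), which gives the cell a
signalling memory of transient exposures — necessary because the active
mediator itself decays in minutes. Myofibroblasts bind with `k_onM`
(default 0.001 (ng/ml)⁻¹min⁻¹, one tenth of the fibroblast `k_on`).

Integration is a fixed-step RK4 batched across all cells (a compiled
kernel), with the substep count chosen from the fastest first-order rate so
the scheme stays well inside its stability region; it matches a `dt = 10⁻³`
min explicit-Euler oracle to better than 10⁻⁴ relative error on a 10-min
step. The cell's local voxel concentration is integrated jointly with the
cell as one extra ODE (net binding depletes the voxel), so TGF-β1 mass is
conserved exactly between field and cells; a frozen-concentration mode
backs the steady-state oracle tests.

## Cellular scale

One living cell per surface voxel. Per 10-minute step, after secretion and
molecular integration: epithelial apoptosis, myofibroblast apoptosis and
deposition, fibroblast differentiation, division, movement — each drawn
per cell, with divisions and moves resolved sequentially in random order.

Cells read the mediator concentrations present at the **start** of the
step; diffusion, decay and latent activation run at the end. With a 2.7-min
active half-life, decaying the field before the cells read it would erase
an exogenous dose before any cell responded, making the 24-h dose-response
calibration protocols unreproducible; the chosen order lets a dose act for
one full step, which is also how a well-stirred bolus behaves over minutes.

* **Differentiation** (per step): eligible only when
  `T/(0.02·P + 0.05) ≥ ratio_diff` (default 30) — a TGF-β1 : PGE~2~ ratio
  gate whose floor term makes it an absolute threshold of ≈1.5 ng/ml when
  PGE~2~ is absent, between the highest non-differentiating (1 ng/ml) and
  lowest differentiating (2 ng/ml) doses observed in vitro. If eligible,
  the cell converts with probability
  `clamp(slope · ΔA_cum / a_max) / (1 + k_inhib_diff · P)`, where `ΔA_cum`
  is the α-SMA synthesized since the previous check — a per-step reading of
  the probability's "amount synthesized", so that differentiation pressure
  tracks current signalling and rescue interventions can act.
* **Epithelial apoptosis** (per step):
  `m·B_T/(B_T + k·B_P) + C` with linear quasi-equilibrium binding
  `B_T = β_T·T`, `B_P = β_P·P` (the 0/0 fraction is defined as 0). `m`,
  `k`, `C` are per-step hazards; defaults `m = 0.2`, `k = 100`, `C = 10⁻⁷`
  were set so that the untreated co-culture reproduces complete epithelial
  survival over 7 days (half a percent attrition) while exogenous doses of
  2–4 ng/ml still produce a measurable, monotone 24-h kill.
* **Proliferation**: fibroblasts divide at `dt·ln2/T_double`
  (`T_double = 24 h`) when local TGF-β1 ≥ `min_prolifTGFB1` (default 0),
  PGE~2~ ≤ `max_prolifPGE2`, and an empty Moore neighbour exists; daughters
  are fresh fibroblasts placed uniformly in an empty neighbour. The PGE~2~
  ceiling defaults to 3 nM: the data bound it only to the open interval
  (1, 10] nM — 1 nM explicitly non-inhibitory, 10 nM inhibitory — and a
  ceiling exactly at a tested dose would put that dose on a knife edge, so
  the log-midpoint of the admissible interval is used. Growth suppression
  at high TGF-β1 is *emergent*: differentiation removes cells from the
  dividing pool.
* **Movement**: only fibroblasts move (probability `p_move = 0.5` per
  step, uniform empty Moore neighbour). Epithelial cells and
  myofibroblasts are stationary.
* **Myofibroblasts** die with probability 3×10⁻⁴ per step (≈3-week mean
  lifetime; myofibroblasts are apoptosis-resistant and persist across a
  7-day run) and deposit ECM plus their latent TGF-β1 secretion onto their
  surface voxel. Latent surface pools activate to the diffusible form at
  `k_act = 0.01` /min.

Baseline mediator tone follows from the secretion defaults: 5000 epithelial
cells at `V_ePGE2 = 3×10⁻¹¹` nmol/cell/min hold ≈4 nM PGE~2~ in the full
well (≈55 nM in the shallower reduced well), enough to keep fibroblasts
quiescent and epithelium protected; 500 fibroblasts at
`k_synL = 1.3×10⁻⁶` ng/cell/min (≈10⁻¹⁶ g/s, the published magnitude) keep
active TGF-β1 in the 0.01–0.03 ng/ml range — a healthy attractor.

## Reduced test profile

All stochastic desk-scale experiments run on a 27 × 27 × 20 voxel lattice
seeded with 550 epithelial cells and 55 fibroblasts — the same areal
densities as the full model. Because the reduced well is shallower, a given
secretion rate produces higher steady concentrations than at full scale;
both mediators scale identically, so ratio-driven behaviour is preserved,
but absolute-threshold behaviour (the proliferation ceiling, the
differentiation gate floor) sits at a different operating point than a
full-depth run. Scenario presets and acceptance experiments are defined on
the reduced profile, so all statements about them are at that scale. The
doubling-time experiment uses a 54 × 54 surface so that 100 seeded
fibroblasts stay far from confluence across the 48-h fitted window.

## Calibration

The 24-h differentiation and apoptosis protocols simulate single-cell-type
cultures with an exogenous uniform active TGF-β1 dose at t = 0 (the dose
then decays; cells respond through their signalling memory). The apoptosis
protocol initializes PGE~2~ at 2 nM — the constitutive epithelial PGE~2~
tone present at plating. This matters structurally: with exactly zero bound
PGE~2~, the apoptosis hazard saturates at `m + C` for *any* positive dose
and the dose response carries no information.

The fitters minimize squared error between a dose-response table and a
forward model, over log-scaled bounded parameters (grid-seeded Nelder-Mead
followed by an L-BFGS-B polish). The default forward model is a
deterministic mean-field map: one average cell per dose, integrated under
the ambient mediator trajectories with the same per-step rules as the ABM
(for apoptosis this reduces to a closed-form product of per-step hazards).
A simulation-in-the-loop objective (`forward = "abm"`, fixed seeds per
evaluation for determinism) is available when stochastic finite-size
effects matter. Synthetic fixture tables are generated from the same
mean-field map plus truncated Gaussian noise, so fitter tests are genuine
round trips: constants are recovered within 20 % (Eq 1) and 25 % (Eq 2)
when the doses exercise the identifying features — for `a_max` that means
doses that push α-SMA toward its cap; `k` is flagged (not errored) as
unidentifiable when the table carries no bound-PGE~2~ signal.

## Sensitivity analysis

Latin hypercube sampling assigns each varied parameter one value per
equal-probability stratum (log-uniform for rate-like parameters, linear for
probabilities and for the proliferation threshold whose baseline is 0),
spanning two orders of magnitude centred on the baseline. The varied set is
the fifteen named mechanisms of the cellular/molecular model plus the
myofibroblast apoptosis and ECM deposition rates and an inert dummy
control; initial conditions and diffusivities are fixed. The full design is
500 sets × 3 replicates = 1500 runs; the desk-scale experiment uses 60
sets × 3 replicates on the reduced profile, evaluated at day 7. Replicates
are averaged per parameter set before ranking so the PRCC t-test uses
N = 60 and is not inflated by pseudo-replication. PRCC follows the standard
construction: rank-transform everything, partial out all other parameters
by linear regression on ranks, correlate residuals, and test with
`t = r·√((N−2−p)/(1−r²))` at p < 0.01.

At desk scale the experiment reliably recovers the qualitative structure —
TGF-β1 synthesis suppresses epithelial survival and drives myofibroblast
differentiation, PGE~2~ synthesis suppresses fibroblast proliferation, the
dummy is never significant — but the *ranking* of the epithelial-survival
correlates is not stable at N = 60: the PGE~2~-side parameters (`k`, β_P,
`V_ePGE2`) compete with TGF-β1 synthesis for the largest magnitude. This is
a structural property of the apoptosis hazard, whose fraction
`B_T/(B_T + k·B_P)` is rank-symmetric in its TGF-β1 and PGE~2~ arguments
when both sides are varied over equal spans; the published experiment used
supplementary per-parameter ranges that are not available, and dominance of
TGF-β1 synthesis evidently depends on them.

## Outcomes, scenarios and interventions

`classify_outcome()` maps a 168-h series to one of four categories with
fixed thresholds (precedence excessive > rapid > gradual > healthy):
excessive = lineage ≥ 4× initial and epithelial survival < 10 %;
rapid = ≥ 50 % epithelial loss within 24 h; gradual = 25–75 % loss at 168 h
with fibroblasts exceeding 2× initial at some time; healthy = ≥ 90 %
survival with < 5 % myofibroblasts. Unmatched series get the nearest
category by the same ordered rules, with a warning — the underlying
outcome space is a continuum.

Three shipped presets (plain-text config overlays on the reduced profile)
land in the three non-healthy categories: `rapid` (TGF-β1 synthesis ×50,
PGE~2~ synthesis ×0.05), `gradual` (TGF-β1 synthesis ×1.15, PGE~2~
synthesis ×0.05) and `excessive` (PGE~2~ synthesis ×0.005 alone — the
collapse of epithelial PGE~2~ is enough to release both proliferation and,
as TGF-β1 accumulates with the growing fibroblast population, delayed
differentiation). Interventions multiply named parameters at t = 0
(defaults 0.1× for "decreased", 10× for "increased"); treated and untreated
arms always share seeds, and the two-hit comparison asks, seed by matched
seed, whether the combined intervention's 168-h epithelial survival is at
least the better single intervention's.

## Problem sizes and numerical choices

Desk-scale experiment sizes used throughout the tests and the acceptance
script, chosen as the smallest sizes at which the respective statistics are
stable: 10 seeds for doubling time (72 h runs, fit over 0–48 h), 10 seeds
per dose for the proliferation panels (48 h), 60 × 3 runs per sensitivity
experiment (168 h), and 10 matched seeds per treatment arm (168 h).
Dose-response tests use 550-cell cultures. Engine tolerances: mediator mass
conservation to 10⁻¹⁰ relative; the joint cell–field TGF-β1 audit closes to
10⁻⁶ relative per 24 h (in practice ~10⁻¹², since binding, uptake and the
voxel concentration are integrated as one system). Ties and degenerate
cases: a fully surrounded cell neither moves nor divides; rank tests use
the normal approximation (counts tie freely); the Eq 2 fraction at
`B_T = B_P = 0` is 0.

## Known limitations

The model inherits the scope of its cellular rules: no epithelial
proliferation or re-epithelialization, no immune compartment, no
mechanotransduction (Rho/ROCK and adhesion signalling are absorbed into the
single coarse-grained signal `S`), no explicit SMAD species, no
low-dose-PGE~2~ proliferative boost (observed in vitro at 0.1 nM but with
no stated model rule), and no lateral transport of ECM or latent TGF-β1.
The synthetic-data generators reproduce the *shapes* the classifier and
fitters must handle, not biological noise structure, so green fixture tests
demonstrate algorithmic correctness rather than biological validity. The
reduced test profile concentrates mediators relative to the full well, as
discussed above; conclusions about absolute thresholds should be drawn at
full scale.
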