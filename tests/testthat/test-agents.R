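ap_default <- agent_params()

test_that("differentiation probability follows Eq 1 with clamping", {
  ap <- agent_params(slope = 0.3, a_max = 10)
  expect_equal(prob_differentiation(0, ap), 0)
  expect_equal(prob_differentiation(10, ap), 0.3)
  expect_equal(prob_differentiation(5, ap), 0.15)
  ap2 <- agent_params(slope = 2, a_max = 10)
  expect_equal(prob_differentiation(10, ap2), 1) # clamped
  expect_true(all(prob_differentiation(seq(0, 100, by = 5), ap2) <= 1))
  expect_error(prob_differentiation(-1, ap))
})

test_that("epithelial apoptosis probability follows Eq 2", {
  ap <- agent_params(m = 0.4, k = 2, C = 0.01)
  expect_equal(prob_epithelial_apoptosis(10, 5, ap), 0.4 * 10 / (10 + 10) + 0.01)
  expect_equal(prob_epithelial_apoptosis(0, 5, ap), 0.01)  # zero ligand -> C
  expect_equal(prob_epithelial_apoptosis(0, 0, ap), 0.01)  # 0/0 fraction is 0
  expect_equal(prob_epithelial_apoptosis(1e12, 5, ap), 0.41,
               tolerance = 1e-6)                           # saturation m + C
  grid <- expand.grid(B_T = c(0, 1, 10, 1e6), B_P = c(0, 1, 50))
  pr <- prob_epithelial_apoptosis(grid$B_T, grid$B_P, ap)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("epithelial binding is linear quasi-equilibrium", {
  ap <- agent_params(beta_T = 1, beta_P = 2)
  cell <- list(kind = "epithelial", B_T = 0, B_P = 0)
  cell <- epithelial_binding_update(cell, 2, 3, ap)
  expect_equal(cell$B_T, 2)
  expect_equal(cell$B_P, 6)
  c2 <- epithelial_binding_update(cell, 4, 3, ap)
  expect_equal(c2$B_T, 2 * cell$B_T) # doubling T doubles B_T
  expect_equal(epithelial_binding_update(cell, 0, 0, ap)$B_T, 0)
  expect_error(epithelial_binding_update(list(kind = "fibroblast"), 1, 1, ap),
               "epithelial")
})

test_that("movement respects contact inhibition and the move probability", {
  spec <- grid_spec(3, 3, 2)
  # fully surrounded: never moves
  occ <- matrix(1L, 3, 3)
  cell <- list(id = 5L, i = 2, j = 2)
  set.seed(1)
  for (r in 1:20) {
    out <- attempt_move(cell, spec, occ, agent_params(p_move = 1))
    expect_equal(c(out$cell$i, out$cell$j), c(2, 2))
  }
  # p_move = 0: never moves even when free
  occ0 <- matrix(0L, 3, 3); occ0[2, 2] <- 5L
  for (r in 1:20) {
    out <- attempt_move(cell, spec, occ0, agent_params(p_move = 0))
    expect_equal(c(out$cell$i, out$cell$j), c(2, 2))
  }
  # empirical move frequency approximates p_move for an isolated cell
  spec9 <- grid_spec(9, 9, 2)
  ap <- agent_params(p_move = 0.5)
  moved <- 0
  set.seed(42)
  for (r in 1:10000) {
    occ1 <- matrix(0L, 9, 9); occ1[5, 5] <- 1L
    out <- attempt_move(list(id = 1L, i = 5, j = 5), spec9, occ1, ap)
    if (out$cell$i != 5 || out$cell$j != 5) moved <- moved + 1
  }
  expect_equal(moved / 10000, 0.5, tolerance = 0.02 / 0.5)
})

test_that("proliferation is gated by both mediators and free space", {
  spec <- grid_spec(5, 5, 2)
  occ <- matrix(0L, 5, 5); occ[3, 3] <- 1L
  cell <- list(id = 1L, i = 3, j = 3)
  ap <- agent_params(min_prolifTGFB1 = 0, max_prolifPGE2 = 3, T_double_h = 24)
  set.seed(2)
  # PGE2 above the ceiling: never divides
  for (r in 1:50)
    expect_null(attempt_proliferation(cell, 1, 10, spec, occ, ap, 10)$daughter)
  # no empty neighbour: never divides
  occf <- matrix(1L, 5, 5)
  for (r in 1:50)
    expect_null(attempt_proliferation(cell, 1, 0, spec, occf, ap, 10)$daughter)
  # permissive: divides at the per-step rate dt ln2 / T_double
  n_div <- 0
  for (r in 1:20000) {
    out <- attempt_proliferation(cell, 1, 0, spec, occ, ap, 10)
    if (!is.null(out$daughter)) {
      n_div <- n_div + 1
      expect_equal(out$daughter$kind, "fibroblast")
      expect_true(abs(out$daughter$i - 3) <= 1 && abs(out$daughter$j - 3) <= 1)
    }
  }
  p_expected <- 10 * log(2) / (24 * 60)
  expect_equal(n_div / 20000, p_expected, tolerance = 0.15)
})

test_that("differentiation needs the mediator-ratio gate and PGE2 brake", {
  ap <- agent_params(ratio_diff = 30, ratio_scale = 0.02, ratio_eps = 0.05,
                     slope = 1, a_max = 1, k_inhib_diff = 0.02)
  cell <- list(kind = "fibroblast")
  set.seed(3)
  # below the gate: never converts regardless of synthesized alpha-SMA
  for (r in 1:50)
    expect_equal(maybe_differentiate(cell, 100, 0.5, 0, ap)$kind, "fibroblast")
  # far above the gate with saturating probability: converts immediately
  expect_equal(maybe_differentiate(cell, 100, 10, 0, ap)$kind, "myofibroblast")
  # extreme PGE2 suppresses conversion even above the ratio gate
  ap2 <- agent_params(ratio_diff = 0, k_inhib_diff = 1e6, slope = 1, a_max = 1)
  for (r in 1:50)
    expect_equal(maybe_differentiate(cell, 100, 10, 5, ap2)$kind, "fibroblast")
})

test_that("myofibroblast apoptosis draws are geometric; survivors deposit", {
  spec <- grid_spec(4, 4, 2)
  cell <- list(kind = "myofibroblast", i = 2, j = 2, alive = TRUE)
  pools <- surface_pools(spec)
  # p = 1 dies immediately; p = 0 survives and deposits
  out1 <- myofibroblast_step(cell, pools, 0.1, agent_params(p_myo_apop = 1))
  expect_false(out1$cell$alive)
  out0 <- myofibroblast_step(cell, pools, 0.1,
                             agent_params(p_myo_apop = 0, q_ecm = 2,
                                          f_lat_surface = 0.5))
  expect_true(out0$cell$alive)
  expect_equal(out0$pools$ecm[2, 2], 2)
  expect_equal(out0$pools$latentTGFB1[2, 2], 0.05)
  # expected lifetime ~ 1/p steps
  ap <- agent_params(p_myo_apop = 0.25)
  set.seed(9)
  lifetimes <- vapply(1:4000, function(r) {
    c1 <- cell; n <- 0
    repeat {
      n <- n + 1
      c1 <- myofibroblast_step(c1, pools, 0, ap)$cell
      if (!c1$alive) return(n)
    }
  }, numeric(1))
  expect_equal(mean(lifetimes), 1 / 0.25, tolerance = 0.05)
})
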