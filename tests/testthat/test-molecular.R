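p_default <- molecular_params()

test_that("ligand-free steady state has zero derivatives and basal secretion", {
  p <- p_default
  st <- molecular_state(R = p$v_R / p$k_tR, p = p)
  d <- molecular_derivatives(st, T_local = 0, P_local = 0, p = p)
  expect_equal(unname(d$dstate), rep(0, 5))
  expect_equal(d$latent_secretion_flux_ng_min, p$b0 * p$k_synL)
  expect_equal(d$ligand_uptake_flux_ng_min, 0)
  expect_error(molecular_derivatives(st, -1, 0, p), "nonnegative")
})

test_that("saturating PGE2 shuts down synthesis", {
  p <- p_default
  st <- molecular_state(R = 1e4, C_s = 100, C_i = 500, A = 2, A_cum = 5, p = p)
  d <- molecular_derivatives(st, T_local = 1, P_local = 1e9, p = p)
  expect_equal(d$dstate[["A"]], -p$k_degA * 2, tolerance = 1e-6)
  expect_lt(d$dstate[["A_cum"]], 1e-6)
  expect_lt(d$latent_secretion_flux_ng_min, 1e-12)
  # monotonicity: more PGE2 never increases alpha-SMA synthesis or secretion
  ds <- vapply(c(0, 1, 10, 100), function(P)
    molecular_derivatives(st, 1, P, p)$dstate[["A_cum"]], numeric(1))
  expect_true(all(diff(ds) <= 1e-12))
  # more ligand never decreases surface binding at C_s = 0
  st0 <- molecular_state(R = 1e4, p = p)
  dT <- vapply(c(0, 0.5, 1, 2), function(Tl)
    molecular_derivatives(st0, Tl, 0, p)$dstate[["C_s"]], numeric(1))
  expect_true(all(diff(dT) >= 0))
})

test_that("integrator matches a fine-step explicit Euler oracle", {
  p <- p_default
  st <- molecular_state(p = p)
  Tl <- 1.2; Pl <- 5
  out <- integrate_molecular(st, Tl, Pl, p, dt_min = 10)
  # brute-force Euler at dt = 1e-3 min with frozen concentrations
  s <- c(unclass(st), U = 0, Ldeg = 0, Lsec = 0, T = Tl)
  h <- 1e-3
  for (i in seq_len(10 / h)) {
    d <- fibrosim:::mol_deriv_mat(matrix(s, 1), Pl, p$k_on, p, omega = 0)
    s <- s + h * d[1, ]
  }
  expect_equal(unname(unclass(out$state)), unname(s[1:5]), tolerance = 1e-4)
  expect_equal(out$uptake_ng, s[["U"]] * fibrosim:::TGFB1_NG_PER_MOLECULE,
               tolerance = 1e-4)
  expect_equal(out$secretion_ng, s[["Lsec"]], tolerance = 1e-4)
})

test_that("integration is consistent under step splitting and vanishing dt", {
  p <- p_default
  st <- molecular_state(C_s = 50, C_i = 100, A = 1, A_cum = 2, p = p)
  one <- integrate_molecular(st, 0.8, 2, p, dt_min = 10)
  half <- integrate_molecular(st, 0.8, 2, p, dt_min = 5)
  two <- integrate_molecular(half$state, 0.8, 2, p, dt_min = 5)
  expect_equal(unclass(two$state), unclass(one$state), tolerance = 1e-5)
  tiny <- integrate_molecular(st, 0.8, 2, p, dt_min = 1e-6)
  expect_equal(unclass(tiny$state), unclass(st), tolerance = 1e-4)
})

test_that("receptor and ligand bookkeeping identities hold over a step", {
  # d(R + C_s + C_i)/dt = v_R - k_tR R - k_degC C_i, so the receptor count
  # change must equal synthesis - turnover - complex degradation; the bound
  # ligand change must equal net uptake - internal processing.
  p <- p_default
  st <- molecular_state(C_s = 20, C_i = 40, p = p)
  S <- matrix(c(unclass(st), 0, 0, 0, 1.5), 1)
  h <- 10 / 2000
  s <- S[1, ]; syn <- 0; turn <- 0; degC <- 0
  for (i in seq_len(2000)) {
    d <- fibrosim:::mol_deriv_mat(matrix(s, 1), 3, p$k_on, p, omega = 0)[1, ]
    syn <- syn + h * p$v_R
    turn <- turn + h * p$k_tR * s[1]
    degC <- degC + h * p$k_degC * s[3]
    s <- s + h * d
  }
  tot0 <- sum(S[1, 1:3]); tot1 <- sum(s[1:3])
  expect_equal(tot1 - tot0, syn - turn - degC,
               tolerance = 1e-8, ignore_attr = TRUE)
  # ligand identity: uptake = Delta(C_s + C_i) + internally processed
  expect_equal(s[6], (s[2] + s[3]) - (S[1, 2] + S[1, 3]) + s[7],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ligand-free relaxation reaches R* = v_R / k_tR", {
  p <- p_default
  st <- molecular_state(R = 100, C_s = 5, C_i = 5, p = p)
  turnover_time <- 1 / p$k_tR
  out <- integrate_molecular(st, 0, 0, p, dt_min = 10 * turnover_time,
                             n_sub = 4000)
  expect_equal(out$state[["R"]], p$v_R / p$k_tR, tolerance = 1e-3)
})

test_that("A_cum never decreases along trajectories", {
  p <- p_default
  set.seed(3)
  for (rep in 1:5) {
    st <- molecular_state(C_s = runif(1, 0, 200), C_i = runif(1, 0, 500),
                          A = 0, A_cum = 0, p = p)
    prev <- 0
    for (s in 1:20) {
      out <- integrate_molecular(st, runif(1, 0, 3), runif(1, 0, 50), p, 10)
      st <- out$state
      expect_gte(st[["A_cum"]], prev - 1e-12)
      expect_lte(st[["A"]], st[["A_cum"]] + 1e-9)
      prev <- st[["A_cum"]]
    }
  }
})

test_that("equilibrium bound fraction is zero at T = 0, monotone, and matches integration", {
  p <- p_default
  expect_equal(equilibrium_bound_fraction(0, p), 0)
  fr <- vapply(c(0, 0.1, 0.5, 1, 2, 5, 20), equilibrium_bound_fraction,
               numeric(1), p = p)
  expect_true(all(diff(fr) >= 0))
  # long-run integration at T = 1 ng/ml
  st <- molecular_state(p = p)
  out <- integrate_molecular(st, 1, 0, p, dt_min = 5000, n_sub = 20000)
  s <- out$state
  frac_num <- s[["C_s"]] / (s[["R"]] + s[["C_s"]] + s[["C_i"]])
  expect_equal(frac_num, equilibrium_bound_fraction(1, p), tolerance = 1e-6)
})
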