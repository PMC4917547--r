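test_that("lattice geometry matches the modelled culture well", {
  spec <- grid_spec()
  expect_equal(total_compartments(spec), 1850202)
  expect_equal(compartments_per_layer(spec), 6561)
  expect_equal(total_volume_ul(spec), 19.70, tolerance = 0.05 / 19.70)
  expect_equal(total_compartments(grid_spec(1, 1, 1)), 1)
  expect_equal(total_compartments(grid_spec(2, 3, 4)), 24)
  expect_equal(total_volume_ul(grid_spec(1, 1, 1, 22)), 1.0648e-5)
  expect_error(grid_spec(0, 81, 282), "positive")
  expect_error(grid_spec(dx_um = 0), "dx_um")
})

test_that("surface Moore neighbourhoods truncate at boundaries", {
  spec <- grid_spec(5, 5, 2)
  expect_equal(nrow(surface_neighbors(spec, 3, 3)), 8)
  expect_equal(nrow(surface_neighbors(spec, 1, 1)), 3)
  expect_equal(nrow(surface_neighbors(spec, 1, 3)), 5)
  nb <- surface_neighbors(spec, 2, 2)
  expect_false(any(nb[, "i"] == 2 & nb[, "j"] == 2)) # self excluded
  expect_error(surface_neighbors(spec, 0, 3), "out of range")
})

test_that("half-life conversion assumes first-order kinetics", {
  expect_equal(halflife_to_rate(2.7), log(2) / 2.7)
  expect_equal(halflife_to_rate(9.2), log(2) / 9.2)
  expect_equal(halflife_to_rate(Inf), 0)
  expect_error(halflife_to_rate(0))
  expect_error(halflife_to_rate(-1))
})

test_that("explicit diffusion matches a dense Laplacian oracle exactly per step", {
  spec <- grid_spec(5, 5, 5, 22)
  n <- total_compartments(spec)
  set.seed(11)
  conc <- array(runif(n), dim = c(5, 5, 5))
  f <- mediator_field(spec, "activeTGFB1", conc, D_cm2_s = 2e-7)
  dt <- 0.5 * (spec$dx_um * 1e-4)^2 / (6 * f$D_cm2_s * 60) # well inside bound
  # dense 7-point Neumann Laplacian built by brute force
  idx <- function(i, j, k) i + 5 * (j - 1) + 25 * (k - 1)
  L <- matrix(0, n, n)
  for (k in 1:5) for (j in 1:5) for (i in 1:5) {
    c0 <- idx(i, j, k)
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5 && kk >= 1 && kk <= 5) {
        L[c0, idx(ii, jj, kk)] <- L[c0, idx(ii, jj, kk)] + 1
        L[c0, c0] <- L[c0, c0] - 1
      }
    }
  }
  alpha <- f$D_cm2_s * 60 * dt / (spec$dx_um * 1e-4)^2
  expected <- as.numeric(conc) + alpha * as.numeric(L %*% as.numeric(conc))
  stepped <- diffusion_decay_step(f, dt, method = "ftcs")
  expect_equal(as.numeric(stepped$conc), expected, tolerance = 1e-13)
  # the implicit scheme solves (I - alpha L) u_new = u per axis split
  imp <- diffusion_decay_step(f, dt, method = "implicit")
  expect_equal(sum(imp$conc), sum(conc), tolerance = 1e-12)
  expect_true(all(imp$conc >= 0))
})

test_that("unstable explicit step is refused, naming the maximum stable dt", {
  spec <- grid_spec(5, 5, 5, 22)
  f <- mediator_field(spec, "PGE2", 1, D_cm2_s = 5e-6)
  expect_error(diffusion_decay_step(f, 10, method = "ftcs"),
               "maximum stable dt")
})

test_that("mass is conserved without decay over many steps, both schemes", {
  spec <- grid_spec(6, 5, 4, 22)
  set.seed(7)
  conc <- array(rexp(total_compartments(spec)), dim = c(6, 5, 4))
  for (method in c("ftcs", "implicit")) {
    f <- mediator_field(spec, "activeTGFB1", conc, D_cm2_s = 2e-7,
                        k_deg_per_min = 0)
    dt <- if (method == "ftcs") 0.9 * fibrosim:::ftcs_max_dt_min(f) else 10
    m0 <- field_total_mass(f)
    for (s in 1:1000) f <- diffusion_decay_step(f, dt, method = method)
    expect_equal(field_total_mass(f), m0, tolerance = 1e-10)
    expect_true(all(f$conc >= 0))
  }
})

test_that("decay-only dynamics follow C0 exp(-kt) at 1, 2, 3 half-lives", {
  spec <- grid_spec(4, 4, 4, 22)
  for (t_half in c(2.7, 9.2)) {
    f <- mediator_field(spec, "activeTGFB1", 5,
                        D_cm2_s = 0, k_deg_per_min = halflife_to_rate(t_half))
    m0 <- field_total_mass(f)
    for (nh in 1:3) {
      steps <- 20
      for (s in seq_len(steps)) f <- diffusion_decay_step(f, t_half / steps)
      expect_equal(field_total_mass(f), m0 / 2^nh, tolerance = 1e-3)
    }
  }
})

test_that("a spreading Gaussian matches the analytic heat kernel", {
  spec <- grid_spec(41, 41, 41, 22)
  D <- 2e-7
  dx_cm <- spec$dx_um * 1e-4
  # start from an analytic Gaussian (sigma0 = 2 dx) and diffuse to sigma1 = 4 dx
  sigma0 <- 2 * dx_cm
  sigma1 <- 4 * dx_cm
  t_min <- (sigma1^2 - sigma0^2) / (2 * D * 60)
  ax <- (seq_len(41) - 21) * dx_cm
  g3 <- function(sigma) {
    g <- exp(-ax^2 / (2 * sigma^2))
    outer(outer(g, g), g)
  }
  f <- mediator_field(spec, "activeTGFB1", array(g3(sigma0), dim = c(41, 41, 41)),
                      D_cm2_s = D)
  dt <- 0.9 * fibrosim:::ftcs_max_dt_min(f)
  n_steps <- ceiling(t_min / dt)
  for (s in seq_len(n_steps)) f <- diffusion_decay_step(f, t_min / n_steps,
                                                        method = "ftcs")
  expected <- g3(sigma1) * (sigma0 / sigma1)^3
  peak <- max(expected)
  expect_lt(max(abs(f$conc - expected)), 0.02 * peak)
})

test_that("latent activation conserves TGF-beta1 mass across the transfer", {
  spec <- grid_spec(5, 5, 3, 22)
  pools <- surface_pools(spec, k_act_per_min = log(2))
  pools <- deposit_to_surface(pools, 2, 3, latent_amount = 1)
  active <- mediator_field(spec, "activeTGFB1", 0)
  out <- activate_latent(pools, active, dt_min = 1) # k_act * dt = ln 2
  expect_equal(out$transferred, 0.5)
  expect_equal(sum(out$pools$latentTGFB1), 0.5)
  expect_equal(field_total_mass(out$active), 0.5, tolerance = 1e-12)
  # k_act = 0: no transfer
  p0 <- surface_pools(spec, k_act_per_min = 0)
  p0 <- deposit_to_surface(p0, 1, 1, latent_amount = 2)
  out0 <- activate_latent(p0, active, 10)
  expect_equal(out0$transferred, 0)
  # mass balance holds on every step for a generic rate
  p1 <- surface_pools(spec, k_act_per_min = 0.03)
  p1 <- deposit_to_surface(p1, 4, 4, latent_amount = 3)
  a1 <- mediator_field(spec, "activeTGFB1", 0)
  for (s in 1:20) {
    before <- sum(p1$latentTGFB1) + field_total_mass(a1)
    out1 <- activate_latent(p1, a1, 10)
    p1 <- out1$pools; a1 <- out1$active
    expect_equal(sum(p1$latentTGFB1) + field_total_mass(a1), before,
                 tolerance = 1e-12)
  }
})

test_that("surface deposits are additive, local, and never touch soluble fields", {
  spec <- grid_spec(4, 4, 2)
  pools <- surface_pools(spec)
  pools <- deposit_to_surface(pools, 2, 2, ecm_amount = 1.5, latent_amount = 0.3)
  pools <- deposit_to_surface(pools, 2, 2, ecm_amount = 0.5, latent_amount = 0.2)
  expect_equal(pools$ecm[2, 2], 2)
  expect_equal(pools$latentTGFB1[2, 2], 0.5)
  expect_equal(sum(pools$ecm), 2) # no lateral transport
  p2 <- deposit_to_surface(pools, 1, 1, 0, 0)
  expect_identical(p2$ecm, pools$ecm)
  expect_error(deposit_to_surface(pools, 1, 1, ecm_amount = -1), "nonnegative")
})
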