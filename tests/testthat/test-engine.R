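# compact run helper used across engine tests
short_cfg <- function(hours = 6, seed = 1L, ...) {
  reduced_config(run = list(duration_h = hours, seed = seed), ...)
}

test_that("seeding places cells on distinct voxels and reports confluence", {
  w <- initialize_culture(sim_config(run = list(seed = 4L)))
  expect_equal(w$confluence, 5500 / 6561)
  expect_equal(round(100 * w$confluence), 84)
  occ <- w$occupancy[w$occupancy > 0]
  expect_equal(length(occ), 5500)
  expect_false(any(duplicated(occ)))
  # zero cells
  w0 <- initialize_culture(sim_config(init = list(n_epithelial = 0L,
                                                  n_fibroblast = 0L)))
  expect_equal(w0$confluence, 0)
  # full surface occupancy, every voxel exactly once
  wf <- initialize_culture(sim_config(init = list(n_epithelial = 6061L,
                                                  n_fibroblast = 500L)))
  expect_equal(wf$confluence, 1)
  expect_equal(sort(wf$occupancy[wf$occupancy > 0]), 1:6561)
  expect_error(initialize_culture(
    sim_config(init = list(n_epithelial = 6562L, n_fibroblast = 0L))),
    "capacity")
})

test_that("an empty culture only decays its mediators", {
  cfg <- reduced_config(init = list(n_epithelial = 0L, n_fibroblast = 0L,
                                    initial_activeTGFB1 = 2, initial_PGE2 = 10),
                        run = list(duration_h = 4, seed = 1L))
  run <- run_simulation(cfg)
  ts <- run$timeseries
  expect_true(all(ts$fibroblasts == 0 & ts$myofibroblasts == 0 &
                    ts$epithelial == 0))
  expect_true(all(diff(ts$active_tgfb1_ng) <= 0))
  expect_true(all(diff(ts$pge2_nmol) <= 0))
  kT <- log(2) / cfg$env$halflife_active_min
  expect_equal(ts$active_tgfb1_ng[nrow(ts)] / ts$active_tgfb1_ng[1],
               exp(-kT * 4 * 60), tolerance = 1e-6)
})

test_that("identical seed and config reproduce the run bit-for-bit", {
  cfg <- short_cfg(hours = 6, seed = 123L)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$timeseries, r2$timeseries)
  r3 <- run_simulation(short_cfg(hours = 6, seed = 124L))
  expect_false(identical(r1$timeseries, r3$timeseries))
})

test_that("occupancy and cell-count bookkeeping stay consistent while stepping", {
  cfg <- short_cfg(hours = 8, seed = 5L)
  set.seed(cfg$run$seed)
  w <- fibrosim:::new_world(cfg)
  for (s in 1:48) {
    w <- fibrosim:::step_world(w, 10)
    live <- which(w$alive[seq_len(w$n)])
    pos <- w$ci[live] + w$spec$nx * (w$cj[live] - 1L)
    expect_false(any(duplicated(pos))) # one living cell per voxel
    expect_setequal(w$occupancy[w$occupancy > 0], live)
    # lineage bookkeeping: fib + myo + lineage deaths = initial + divisions
    kinds <- w$kind[live]
    n_fib <- sum(kinds == 1L); n_myo <- sum(kinds == 2L)
    expect_equal(n_fib + n_myo + w$counters$myofibroblast_deaths,
                 cfg$init$n_fibroblast + w$counters$divisions)
  }
})

test_that("TGF-beta1 mass audit closes over 24 h of co-culture", {
  cfg <- reduced_config(run = list(duration_h = 24, seed = 11L),
                        init = list(initial_activeTGFB1 = 0.5))
  run <- run_simulation(cfg)
  last <- run$timeseries[nrow(run$timeseries), ]
  supplied <- last$cum_secreted_latent_ng + run$timeseries$active_tgfb1_ng[1]
  accounted <- last$latent_tgfb1_ng + last$active_tgfb1_ng +
    last$cum_degraded_latent_ng + last$cum_degraded_active_ng +
    last$cell_bound_tgfb1_ng + last$cum_internal_degraded_ng
  expect_equal(accounted, supplied, tolerance = 1e-6)
})

test_that("the healthy baseline preserves the epithelium for a week", {
  for (s in 1:10) {
    run <- run_simulation(reduced_config(run = list(seed = s)),
                          keep_state = FALSE)
    last <- run$timeseries[nrow(run$timeseries), ]
    expect_gte(last$epithelial, 0.99 * 550)
    expect_equal(last$myofibroblasts, 0)
    expect_equal(classify_outcome(run), "healthy")
  }
})

test_that("outcome classification follows the narrative rules", {
  base <- function(epi, fib, myo, t = seq(0, 168)) {
    tibble::tibble(time_h = t, epithelial = epi, fibroblasts = fib,
                   myofibroblasts = myo)
  }
  t <- seq(0, 168)
  # flat series: healthy
  expect_equal(classify_outcome(base(rep(5000, 169), rep(500, 169),
                                     rep(0, 169))),
               "healthy")
  # >= 50% epithelial loss in the first 24 h with full early differentiation
  rapid <- base(round(5000 * exp(-log(2) / 12 * t)),
                round(500 * exp(-t / 6)),
                round(500 * (1 - exp(-t / 6))))
  expect_equal(classify_outcome(rapid), "rapid_epi_death_with_differentiation")
  # fibroblasts double by 48 h, about half the epithelium lost by 168 h
  gradual <- base(round(5000 * (1 - 0.5 * t / 168)),
                  round(500 * pmin(3, 2^(t / 42))), rep(0, 169))
  expect_equal(classify_outcome(gradual), "gradual_epi_death_with_proliferation")
  # massive proliferation + differentiation, epithelium nearly gone
  excess <- base(round(5000 * exp(-log(2) / 25 * t)),
                 round(500 + 2000 * stats::plogis((t - 60) / 10) *
                         (1 - stats::plogis((t - 120) / 8))),
                 round(2500 * stats::plogis((t - 120) / 8)))
  expect_equal(classify_outcome(excess),
               "excessive_proliferation_and_differentiation")
  expect_error(classify_outcome(base(rep(1, 10), rep(1, 10), rep(0, 10),
                                     t = 1:10)), "too short")
})

test_that("snapshot export writes consistent plain-text tables", {
  cfg <- short_cfg(hours = 1, seed = 2L)
  run <- run_simulation(cfg, keep_state = TRUE)
  dir <- withr::local_tempdir()
  paths <- write_snapshot(run, dir)
  expect_true(all(file.exists(paths)))
  vox <- utils::read.delim(paths[1])
  expect_equal(nrow(vox), 27 * 27 * 20)
  expect_true(all(vox$activeTGFB1 >= 0))
  cells <- utils::read.delim(paths[3])
  expect_equal(sum(cells$alive & cells$kind == "epithelial"),
               run$timeseries$epithelial[nrow(run$timeseries)])
})
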