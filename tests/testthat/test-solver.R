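test_that("the initial state is homogeneous with a mean-preserving tilt", {
  grid <- discretize(cell_geometry(3), 60)
  tot <- min_totals()

  y0 <- initial_state(grid, tot, tilt = 0)
  expect_true(all(y0["D", ] == 1389))
  expect_true(all(y0["E2", ] == 486))
  expect_true(all(y0[c("d", "d2", "e2", "d2e2"), ] == 0))

  y1 <- initial_state(grid, tot, tilt = 1e-3)
  # pole-to-pole difference of 0.2% of the mean, volume-weighted mean intact
  # pole-most cell centres sit half a cell inside the tips
  expect_equal(unname(y1["D", grid$n] - y1["D", 1]) / 1389, 0.002,
               tolerance = 0.02)
  expect_equal(sum(y1["D", ] * grid$volume) / sum(grid$volume), 1389,
               tolerance = 1e-12)
  # total monomer equivalents are concentration times volume
  expect_equal(sum(y1["D", ] * grid$volume), 1389 * sum(grid$volume),
               tolerance = 1e-12)
})

test_that("diffusion leaves spatially uniform fields unchanged", {
  grid <- discretize(cell_geometry(3), 40)
  # diffusion only: all reaction rates zero
  p0 <- min_rates(omega_db = 0, omega_edf = 0, omega_dim = 0,
                  omega_hydr = 0, omega_eb = 0, omega_er = 0,
                  D_D = 16, D_E = 20, D_m = 0.1)
  y <- matrix(rep(c(100, 50, 7, 5, 3, 2), grid$n), 6, grid$n)
  minde:::stage_model(p0, grid)
  out <- minde:::integrate_staged(as.vector(y), c(0, 50),
                                  sim_config())
  expect_equal(out[2, -1], as.vector(y), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the compiled kinetics agree with the R reference on a grid", {
  # independent route: assemble the same ODE system from the exported
  # pointwise reaction and flux functions and integrate it with an R rhs
  grid <- discretize(cell_geometry(2), 24)
  p <- min_preset("fully_labelled")
  tot <- min_totals()
  y0 <- initial_state(grid, tot, tilt = 1e-3)

  ref_rhs <- function(t, y, parms) {
    f <- matrix(y, 6, grid$n, dimnames = list(minde:::.species, NULL))
    dy <- matrix(0, 6, grid$n, dimnames = list(minde:::.species, NULL))
    for (i in seq_len(grid$n)) {
      s <- f[, i]
      mr <- membrane_reaction_rates(s, p)
      ex <- exchange_fluxes(s, p)
      dy[c("d", "d2", "e2", "d2e2"), i] <- mr
      dy[c("D", "E2"), i] <- ex * grid$area[i] / grid$volume[i]
    }
    dc <- c(D = p$D_D, E2 = p$D_E, d = p$D_m, d2 = p$D_m / 2,
            e2 = p$D_m / 2, d2e2 = p$D_m / 4)
    for (sp in minde:::.species) {
      g <- if (sp %in% c("D", "E2")) grid$cond_cyt else grid$cond_mem
      w <- if (sp %in% c("D", "E2")) grid$volume else grid$area
      flux <- dc[[sp]] * g * diff(f[sp, ])
      dy[sp, ] <- dy[sp, ] + c(flux, 0) / w - c(0, flux) / w
    }
    list(as.vector(dy))
  }

  ref <- deSolve::lsode(as.vector(y0), c(0, 5), ref_rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  minde:::stage_model(p, grid)
  out <- minde:::integrate_staged(as.vector(y0), c(0, 5),
                                  sim_config(rtol = 1e-9, atol = 1e-9))
  expect_equal(out[2, -1], ref[2, -1], tolerance = 1e-6)
})

test_that("totals are conserved without growth or production", {
  traj <- run_fixed_length(3, min_preset("fully_labelled"),
                           sim_config(burn_in = 0, duration = 300,
                                      record_interval = 50))
  tot <- protein_totals(traj)
  expect_lt(diff(range(tot$minD)) / mean(tot$minD), 1e-8)
  expect_lt(diff(range(tot$minE_dimers)) / mean(tot$minE_dimers), 1e-8)
  # non-negativity up to integrator round-off
  expect_gt(min(traj$fields), -1e-12 * mean(traj$fields))
})

test_that("a zero tilt preserves mirror symmetry at round-off level", {
  traj <- run_fixed_length(3, min_preset("fully_labelled"),
                           sim_config(burn_in = 0, duration = 100,
                                      tilt = 0, record_interval = 100))
  f <- traj$fields
  n <- dim(f)[2]
  asym <- max(abs(f[2, , ] - f[2, n:1, ])) / max(f)
  expect_lt(asym, 1e-9)
})

test_that("integration is insensitive to grid and tolerance refinement", {
  cfg <- sim_config(burn_in = 600, duration = 600)
  p <- min_preset("fully_labelled")
  per <- estimate_period(collapse(run_fixed_length(3.5, p, cfg)))
  per_n <- estimate_period(collapse(run_fixed_length(
    3.5, p, sim_config(burn_in = 600, duration = 600, n_cells = 140))))
  per_t <- estimate_period(collapse(run_fixed_length(
    3.5, p, sim_config(burn_in = 600, duration = 600,
                       rtol = 1e-9, atol = 1e-9))))
  expect_lt(abs(per_n - per) / per, 0.02)
  expect_lt(abs(per_t - per) / per, 0.02)
})

test_that("growing cells keep their mean concentrations near target", {
  traj <- run_growing(2.4, 2.7, 1.05e-3, min_preset("partially_labelled"),
                      sim_config(burn_in = 300, record_interval = 5))
  tot <- protein_totals(traj)
  v <- rowSums(traj$volume)
  expect_lt(max(abs(tot$minD / v - 1389) / 1389), 0.01)
  expect_lt(max(abs(tot$minE_dimers / v - 486) / 486), 0.01)
  # recorded geometry is frozen per integration window, so the last
  # snapshot's length lags the target by at most one window of growth
  expect_equal(max(traj$length), 2.7, tolerance = 5e-3)
})

test_that("a vanishing growth rate approaches the fixed-length dynamics", {
  p <- min_preset("partially_labelled")
  cfg <- sim_config(burn_in = 200, duration = 100, record_interval = 100)
  fixed <- run_fixed_length(2.5, p, cfg)
  slow <- run_growing(2.5, 2.5 + 1e-6 * 100, 1e-6, p,
                      sim_config(burn_in = 200, record_interval = 100))
  i <- length(slow$times)
  expect_equal(slow$fields[i, , ], fixed$fields[length(fixed$times), , ],
               tolerance = 1e-3)
})

test_that("division conserves protein through the constriction", {
  sch <- constriction_schedule(t_start = 50, ramp_duration = 432)
  traj <- run_division(3.5, min_preset("partially_labelled"), sch,
                       sim_config(burn_in = 200, duration = 500,
                                  record_interval = 10))
  tot <- protein_totals(traj)
  expect_lt(diff(range(tot$minD)) / mean(tot$minD), 1e-4)
  expect_lt(diff(range(tot$minE_dimers)) / mean(tot$minE_dimers), 1e-4)
  expect_equal(min(traj$septum_radius), 0.077, tolerance = 1e-6)
})
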