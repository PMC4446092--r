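test_that("the period estimator recovers known frequencies", {
  k <- synthetic_kymograph(function(xr, t) 100 + 10 * sin(2 * pi * t / 83),
                           nt = 512)
  p <- estimate_period(k, window = c(0, 511))
  expect_lt(abs(p - 83), 83 / 30)  # within a refined frequency bin

  k0 <- synthetic_kymograph(function(xr, t) 100 + 0 * t)
  expect_true(is.na(estimate_period(k0)))

  # pole-to-pole switching: the pole signal fundamental is the full cycle
  k2 <- synthetic_kymograph(function(xr, t)
    100 + 50 * cos(pi * xr) * cos(2 * pi * t / 60))
  expect_lt(abs(estimate_period(k2) - 60), 3)
})

test_that("constructed standing waves classify by spatial order", {
  om <- 2 * pi / 40
  k1 <- synthetic_kymograph(function(xr, t)
    100 + 40 * cos(pi * xr) * cos(om * t), L = 4)
  r1 <- classify(k1)
  expect_equal(r1$class, "first_order_breather")
  expect_equal(r1$node_positions, 2, tolerance = 0.1)

  k2 <- synthetic_kymograph(function(xr, t)
    100 + 40 * cos(2 * pi * xr) * cos(om * t), L = 4)
  r2 <- classify(k2)
  expect_equal(r2$class, "second_order_breather")
  expect_equal(sort(r2$node_positions), c(1, 3), tolerance = 0.15)
  expect_equal(length(r2$antinode_positions), 3)

  # travelling wave: balanced mode power with drifting phase
  kt <- synthetic_kymograph(function(xr, t)
    100 + 40 * cos(2 * pi * xr - om * t), L = 4)
  expect_equal(classify(kt)$class, "mixed_travelling")

  kc <- synthetic_kymograph(function(xr, t) 100 + xr)
  expect_equal(classify(kc)$class, "stationary")
})

test_that("a detached alternating antinode classifies as midcell", {
  om <- 2 * pi / 40
  bump <- function(c0, w, xr) exp(-(xr - c0)^2 / (2 * w^2))
  # high-MinD phase near one pole alternating with a band by the midline,
  # with the complementary half-cell depletion riding along (mass seesaw)
  k <- synthetic_kymograph(function(xr, t) {
    ph <- (sin(om * t) + 1) / 2
    100 + 60 * (ph * bump(0.95, 0.08, xr) + (1 - ph) * bump(0.40, 0.10, xr)) -
      25 * (2 * ph - 1) * cos(pi * xr)
  }, L = 4)
  expect_equal(classify(k)$class, "midcell_antinode")
})

test_that("classification is invariant to rescaling, shift and mirror", {
  om <- 2 * pi / 50
  f <- function(xr, t) 100 + 30 * cos(pi * xr) * cos(om * t) +
    5 * cos(2 * pi * xr) * cos(om * t / 2)
  k <- synthetic_kymograph(f, L = 5)
  r <- classify(k)

  k_scaled <- k; k_scaled$signal <- 7.5 * k$signal
  r_s <- classify(k_scaled)
  expect_equal(r_s$class, r$class)
  expect_equal(r_s$period, r$period, tolerance = 1e-8)

  k_shift <- synthetic_kymograph(function(xr, t) f(xr, t + 13), L = 5)
  expect_equal(classify(k_shift)$class, r$class)

  k_mirror <- k; k_mirror$signal <- k$signal[, ncol(k$signal):1]
  r_m <- classify(k_mirror)
  expect_equal(r_m$class, r$class)
  expect_equal(r_m$period, r$period, tolerance = 1e-6)
  expect_equal(sort(5 - r_m$node_positions), sort(r$node_positions),
               tolerance = 0.1)
})

test_that("midcell node check rejects flat and offset-node patterns", {
  k0 <- synthetic_kymograph(function(xr, t) 100 + 0 * t)
  expect_false(midcell_node_check(k0))

  om <- 2 * pi / 40
  k1 <- synthetic_kymograph(function(xr, t)
    100 + 40 * cos(pi * xr) * cos(om * t), L = 3.5)
  expect_true(midcell_node_check(k1))

  # an off-centre node pattern fails the midcell-variance criterion
  k2 <- synthetic_kymograph(function(xr, t)
    100 + 40 * cos(pi * (xr^0.6)) * cos(om * t), L = 3.5)
  expect_false(midcell_node_check(k2))
})

test_that("partition metrics are exact on constructed trajectories", {
  grid <- discretize(cell_geometry(3), 40)
  nt <- 5
  f <- array(0, c(nt, grid$n, 6),
             dimnames = list(NULL, NULL, minde:::.species))
  f[, , "D"] <- 1000; f[, , "E2"] <- 400
  f[, , "d2"] <- matrix(rep(grid$x_mid, each = nt), nt)  # asymmetric load
  traj <- structure(list(
    times = seq(0, 40, length.out = nt),
    fields = f,
    x = matrix(grid$x_mid, nt, grid$n, byrow = TRUE),
    volume = matrix(grid$volume, nt, grid$n, byrow = TRUE),
    area = matrix(grid$area, nt, grid$n, byrow = TRUE),
    dx = matrix(grid$dx, nt, grid$n, byrow = TRUE),
    length = rep(3, nt), septum_radius = rep(0.5, nt),
    grid = grid, schedule = NULL), class = "minde_trajectory")

  pm <- partition_metrics(traj)
  # MinE is symmetric: exactly half on top at every time
  expect_equal(pm$frac_minE_top, rep(50, nt), tolerance = 1e-9)
  # the membrane dimer load increases with x, so MinD leans to the top
  expect_true(all(pm$frac_minD_top > 50))
  m <- attr(pm, "metrics")
  expect_equal(m$rms_from_parity_minE, 0, tolerance = 1e-9)
  expect_gt(m$rms_from_parity_minD, 0)

  # symmetric variant: everything at parity
  f[, , "d2"] <- 1
  traj$fields <- f
  pm <- partition_metrics(traj)
  expect_equal(pm$frac_minD_top, rep(50, nt), tolerance = 1e-9)
  expect_equal(attr(pm, "metrics")$rms_D_vs_E, 0, tolerance = 1e-9)
})

test_that("kymograph collapse conserves the axial integral", {
  traj <- run_fixed_length(2.5, min_preset("partially_labelled"),
                           sim_config(burn_in = 100, duration = 100,
                                      record_interval = 25))
  k <- collapse(traj)
  tot <- protein_totals(traj)
  expect_equal(rowSums(k$signal * k$dx), tot$minD, tolerance = 1e-9)
  expect_true(all(k$signal >= 0))

  # uniform cytosol-only state: signal proportional to cross-section
  grid <- traj$grid
  y <- initial_state(grid, min_totals(), tilt = 0)
  sig <- (y["D", ] * grid$volume) / grid$dx
  expect_equal(sig / max(sig),
               grid$volume / grid$dx / max(grid$volume / grid$dx))
})

test_that("the published rates keep a definite midcell node at 3.5 um", {
  cfg <- sim_config(burn_in = 600, duration = 600)
  k <- collapse(run_fixed_length(3.5, min_preset("fully_labelled"), cfg))
  expect_true(midcell_node_check(k))

  # far below the robustness range the oscillation collapses entirely
  k_slow <- collapse(run_fixed_length(3.5, min_rates(omega_hydr = 0.03), cfg))
  expect_false(midcell_node_check(k_slow))
  expect_equal(classify(k_slow)$class, "stationary")
})
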