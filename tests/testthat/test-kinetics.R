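test_that("membrane reaction terms evaluate to their closed forms", {
  p <- min_preset("fully_labelled")

  # identity case
  r0 <- membrane_reaction_rates(point_state(), p)
  expect_equal(unname(r0), rep(0, 4))

  # dimerisation consumes two monomers per dimer formed
  r <- membrane_reaction_rates(point_state(d = 1), p)
  expect_equal(r[["d"]], -0.004)
  expect_equal(r[["d2"]], 0.002)

  # heterotetramer formation, isolated by zeroing the other rates
  p_edf <- min_rates(omega_db = 0, omega_edf = 22, omega_dim = 0,
                     omega_hydr = 0, omega_eb = 0, omega_er = 0,
                     D_D = 0, D_E = 0, D_m = 0)
  r <- membrane_reaction_rates(point_state(d2 = 2, e2 = 1), p_edf)
  expect_equal(r[["d2e2"]], 44)
  expect_equal(r[["d2"]], -44)
  expect_equal(r[["e2"]], -44)

  expect_error(membrane_reaction_rates(c(D = -1, E2 = 0, d = 0, d2 = 0,
                                         e2 = 0, d2e2 = 0), p),
               "non-negative")
})

test_that("exchange fluxes follow the membrane-to-cytosol sign convention", {
  p <- min_preset("fully_labelled")

  # net binding of cytosolic MinD onto an empty membrane
  f <- exchange_fluxes(point_state(D = 1389), p)
  expect_equal(f[["D"]], -5556)

  # MinE release at 30 per second
  f <- exchange_fluxes(point_state(e2 = 1), p)
  expect_equal(f[["E2"]], 30)

  # hydrolysis releases two MinD monomers per heterotetramer
  f <- exchange_fluxes(point_state(d2e2 = 1), p)
  expect_equal(f[["D"]], 0.24)
})

test_that("reactions conserve MinD monomer and MinE dimer equivalents", {
  p <- min_preset("fully_labelled")
  for (s in random_states(25)) {
    mr <- membrane_reaction_rates(s, p)
    ex <- exchange_fluxes(s, p)
    # per unit membrane area: what leaves the membrane enters the cytosol
    # (zero up to cancellation round-off on the large bilinear terms)
    scale_d <- max(abs(mr), abs(ex[["D"]]), 1)
    expect_lt(abs(mr[["d"]] + 2 * mr[["d2"]] + 2 * mr[["d2e2"]] +
                    ex[["D"]]) / scale_d, 1e-12)
    expect_lt(abs(mr[["e2"]] + mr[["d2e2"]] + ex[["E2"]]) / scale_d, 1e-12)
  }
})

test_that("no species is consumed below zero and bilinear terms vanish", {
  p <- min_preset("fully_labelled")
  for (s in random_states(10, seed = 7)) {
    for (sp in c("d", "d2", "e2", "d2e2")) {
      s0 <- unclass(s); s0[sp] <- 0
      r <- membrane_reaction_rates(s0, p)
      expect_gte(r[[sp]], 0)
    }
  }
  # either factor zero kills the complex-formation term
  r <- membrane_reaction_rates(point_state(d2 = 5), p)
  expect_equal(r[["d2e2"]], 0)
  r <- membrane_reaction_rates(point_state(e2 = 5), p)
  expect_equal(r[["d2e2"]], 0)
})

test_that("Boltzmann scaling of the hydrolysis rate behaves", {
  p <- min_preset("fully_labelled")
  ts <- temperature_scaling()
  expect_equal(boltzmann_scaled_hydr(p, 305.15, ts), p$omega_hydr)

  # closed-form evaluation at 37 C
  R <- 1.98720425864083e-3
  expected <- 0.12 * exp(11.5 * 5 / (R * 310.15 * 305.15))
  expect_equal(boltzmann_scaled_hydr(p, 310.15, ts), expected,
               tolerance = 1e-12)

  # strictly increasing in temperature for positive activation energy
  temps <- seq(283.15, 313.15, by = 5)
  vals <- sapply(temps, boltzmann_scaled_hydr, rates = p, scaling = ts)
  expect_true(all(diff(vals) > 0))
  expect_error(boltzmann_scaled_hydr(p, -3, ts), "positive")
})

test_that("MinE equilibrium partitioning reproduces the rate-ratio argument", {
  p <- min_preset("fully_labelled")
  eq <- mine_equilibrium_partition(p)
  expect_equal(eq$rate_ratio, 30 / 0.07)
  expect_lt(abs(eq$rate_ratio - 430), 2)
  expect_lt(abs(100 * eq$cytoplasmic_fraction - 99.75), 0.05)

  # symmetric rates split MinE evenly under the unit-length convention
  eq <- mine_equilibrium_partition(min_rates(omega_eb = 1, omega_er = 1))
  expect_equal(eq$cytoplasmic_fraction, 0.5)

  eq <- mine_equilibrium_partition(min_rates(omega_eb = 0))
  expect_equal(eq$cytoplasmic_fraction, 1)
  expect_identical(eq$rate_ratio, Inf)
})

test_that("presets carry the published constants and differ in two fields", {
  fl <- min_preset("fully_labelled")
  expect_equal(unclass(fl)[c("omega_db", "omega_edf", "omega_dim",
                             "omega_hydr", "omega_eb", "omega_er",
                             "D_D", "D_E", "D_m")],
               list(omega_db = 4, omega_edf = 22, omega_dim = 0.002,
                    omega_hydr = 0.12, omega_eb = 0.07, omega_er = 30,
                    D_D = 16, D_E = 20, D_m = 0.1))
  pl <- min_preset("partially_labelled")
  expect_equal(pl$omega_hydr, 0.5)
  expect_equal(pl$D_D, 24)
  diffs <- names(fl)[mapply(function(a, b) !identical(a, b), fl, pl)]
  expect_setequal(diffs, c("omega_hydr", "D_D"))
  expect_error(min_preset("unlabelled"))
})

test_that("totals validate and default to the published concentrations", {
  tot <- min_totals()
  expect_equal(tot$minD_total, 1389)
  expect_equal(tot$minE_dimer_total, 486)
  expect_error(min_totals(minD_total = -1), "positive")
})

test_that("rate presets round-trip through YAML", {
  p <- min_preset("partially_labelled")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rates_yaml(p, path, totals = min_totals(1000, 300))
  back <- read_rates_yaml(path)
  expect_equal(unclass(back$rates), unclass(p))
  expect_equal(back$totals$minD_total, 1000)
})
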