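# shared fixtures: fast configurations and synthetic kymographs

fast_config <- function(...) {
  sim_config(burn_in = 300, duration = 400, ...)
}

# build a minde_kymograph from a signal function f(x_rel, t) on a uniform
# grid, for classifier tests with known ground truth
synthetic_kymograph <- function(f, L = 4, nt = 256, nx = 60, dt = 1) {
  times <- seq(0, by = dt, length.out = nt)
  xm <- (seq_len(nx) - 0.5) * (L / nx)
  sig <- outer(times, xm / L, function(t, xr) f(xr, t))
  structure(list(
    times = times,
    x = matrix(xm, nt, nx, byrow = TRUE),
    x_rel = matrix(xm / L, nt, nx, byrow = TRUE),
    signal = sig,
    dx = matrix(L / nx, nt, nx),
    length = rep(L, nt),
    septum_radius = rep(0.5, nt)), class = "minde_kymograph")
}

# deterministic pseudo-random point states for property loops
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    point_state(D = runif(1, 0, 2000), E2 = runif(1, 0, 800),
                d = runif(1, 0, 3000), d2 = runif(1, 0, 2000),
                e2 = runif(1, 0, 50), d2e2 = runif(1, 0, 2000))
  })
}
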