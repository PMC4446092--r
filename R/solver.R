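#' Simulation configuration
#'
#' @param n_cells number of axial finite-volume cells, or `NULL` to target a
#'   0.05 um cell width for the current geometry.
#' @param burn_in equilibration time before recording, s (default 1000):
#'   the system is run without growth from the homogeneous initial state so
#'   that it converges to its stable pattern.
#' @param duration recorded simulation time, s.
#' @param record_interval spacing of recorded snapshots, s.
#' @param tilt relative amplitude of the deterministic linear perturbation
#'   applied to the initial cytosolic MinD field to break the pole-pole
#'   symmetry reproducibly (default 1e-3).
#' @param production hold the cell-mean MinD and MinE concentrations at
#'   their targets by homogeneous cytosolic production (default `NULL`:
#'   enabled for growing runs, disabled otherwise).
#' @param production_tau relaxation time of the production controller, s.
#' @param rtol,atol relative and absolute integration tolerances.
#' @param dt_max largest internal step the integrator may take, s.
#' @param maxsteps internal step budget per integration call.
#' @return An object of class `minde_config`.
#' @export
sim_config <- function(n_cells = NULL, burn_in = 1000, duration = 1000,
                       record_interval = 1, tilt = 1e-3, production = NULL,
                       production_tau = 1, rtol = 1e-7, atol = 1e-7,
                       dt_max = 5, maxsteps = 5e5) {
  structure(list(n_cells = n_cells, burn_in = burn_in, duration = duration,
                 record_interval = record_interval, tilt = tilt,
                 production = production, production_tau = production_tau,
                 rtol = rtol, atol = atol, dt_max = dt_max,
                 maxsteps = maxsteps),
            class = "minde_config")
}

.species <- c("D", "E2", "d", "d2", "e2", "d2e2")

#' Homogeneous initial state with a symmetry-breaking tilt
#'
#' All MinD starts in the cytosolic D state and all MinE in the cytosolic E2
#' state, uniformly distributed; membrane species start empty.  A linear
#' axial tilt of relative amplitude `tilt` is applied to D (pole-to-pole
#' difference `2 * tilt` of the mean, volume-weighted mean unchanged on the
#' symmetric grid) so that the pole that wins the first oscillation is fixed
#' by construction rather than by round-off noise.
#'
#' @param grid a `minde_grid` from [discretize()].
#' @param totals a [min_totals()] object.
#' @param tilt relative tilt amplitude.
#' @return A 6 x n matrix of class `minde_fields` (rows = species).
#' @export
initial_state <- function(grid, totals = min_totals(), tilt = 1e-3) {
  n <- grid$n
  L <- grid$geom$length
  f <- matrix(0, 6, n, dimnames = list(.species, NULL))
  f["D", ] <- totals$minD_total * (1 + tilt * (2 * grid$x_mid / L - 1))
  f["E2", ] <- totals$minE_dimer_total
  structure(f, class = "minde_fields")
}

# stage rate constants and grid arrays into the compiled right-hand side
stage_model <- function(rates, grid, dilution = 0, production = FALSE,
                        totals = NULL, tau = 1) {
  opts <- c(dilution,
            if (production) tau else 0,
            if (production) totals$minD_total else 0,
            if (production) totals$minE_dimer_total else 0,
            sum(grid$volume))
  .Call(C_minde_setup,
        as.double(unlist(rates)),
        as.double(grid$volume), as.double(grid$area),
        as.double(grid$cond_cyt), as.double(grid$cond_mem),
        as.integer(grid$is_cylinder), as.double(opts))
}

# one deSolve integration over `times` for the staged model
integrate_staged <- function(y, times, config) {
  out <- deSolve::lsode(
    y = as.vector(y), times = times, func = "minde_derivs", parms = NULL,
    dllname = "minde", initfunc = "minde_initmod",
    jactype = "bandint", bandup = 6L, banddown = 6L,
    rtol = config$rtol, atol = config$atol,
    hmax = config$dt_max, maxsteps = config$maxsteps)
  att <- attributes(out)
  if (!is.null(att$istate) && att$istate[1] < 0)
    stop("integration failure (lsode istate ", att$istate[1], ")")
  if (any(!is.finite(out[, -1])))
    stop("integration produced non-finite concentrations")
  out
}

n_cells_for <- function(config, L) {
  if (!is.null(config$n_cells)) config$n_cells else max(20L, round(L / 0.05))
}

# accumulate snapshots into a trajectory object
new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$times <- list(); env$fields <- list(); env$grids <- list()
  env
}

record_rows <- function(rec, out, grid, t_offset = 0) {
  ts <- out[, 1] + t_offset
  for (i in seq_along(ts)) {
    k <- length(rec$times) + 1L
    rec$times[[k]] <- ts[i]
    rec$fields[[k]] <- matrix(out[i, -1], 6, grid$n,
                              dimnames = list(.species, NULL))
    rec$grids[[k]] <- grid
  }
}

finish_trajectory <- function(rec, rates, config, totals, kind,
                              schedule = NULL) {
  times <- unlist(rec$times)
  T_ <- length(times); n <- ncol(rec$fields[[1]])
  arr <- array(NA_real_, c(T_, n, 6), dimnames = list(NULL, NULL, .species))
  x <- volume <- area <- dx <- matrix(NA_real_, T_, n)
  L <- r_min <- numeric(T_)
  for (i in seq_len(T_)) {
    arr[i, , ] <- t(rec$fields[[i]])
    g <- rec$grids[[i]]
    x[i, ] <- g$x_mid; volume[i, ] <- g$volume; area[i, ] <- g$area
    dx[i, ] <- g$dx
    L[i] <- g$geom$length
    r_min[i] <- if (is.null(g$geom$constriction)) g$geom$radius else
      g$geom$constriction$r_min
  }
  structure(list(times = times, fields = arr, x = x, volume = volume,
                 area = area, dx = dx, length = L, septum_radius = r_min,
                 grid = rec$grids[[T_]], rates = rates, config = config,
                 totals = totals, kind = kind, schedule = schedule),
            class = "minde_trajectory")
}

#' Simulate a cell of fixed length
#'
#' Burns in from the homogeneous tilted initial state, then records the
#' trajectory at `record_interval`.  Reported times start at zero at the end
#' of burn-in.  Deterministic given the configuration.
#'
#' @param L cell length, um (at least 1).
#' @param rates a [min_rates()] object.
#' @param config a [sim_config()].
#' @param totals a [min_totals()] object.
#' @return A `minde_trajectory`.
#' @export
#' @examples
#' \donttest{
#' traj <- run_fixed_length(3.5, min_preset("fully_labelled"),
#'                          sim_config(duration = 400))
#' classify(collapse(traj))
#' }
run_fixed_length <- function(L, rates, config = sim_config(),
                             totals = min_totals()) {
  if (L < 1) stop("cell length below 1 um")
  grid <- discretize(cell_geometry(L), n_cells_for(config, L))
  y <- initial_state(grid, totals, config$tilt)
  production <- isTRUE(config$production)
  stage_model(rates, grid, production = production, totals = totals,
              tau = config$production_tau)
  if (config$burn_in > 0) {
    out <- integrate_staged(y, c(0, config$burn_in), config)
    y <- out[2, -1]
  }
  rec <- new_recorder()
  times <- seq(0, config$duration, by = config$record_interval)
  out <- integrate_staged(y, times, config)
  record_rows(rec, out, grid)
  finish_trajectory(rec, rates, config, totals, kind = "fixed")
}

#' Simulate a growing cell
#'
#' The cell burns in at its starting length, then the cylindrical section is
#' stretched linearly in time.  Each species in the cylinder receives the
#' growing-domain dilution decay `-growth_rate * c / L_cylinder`, and
#' homogeneous cytosolic production of D and E2 holds the cell-mean MinD and
#' MinE concentrations at their targets (within about 1%).  Geometry is
#' refreshed on short integration windows; concentrations ride with their
#' (Lagrangian) cells between refreshes.
#'
#' @param L0,L1 starting and final length, um.
#' @param growth_rate elongation rate, um s^-1 (e.g. 0.625e-3 for the
#'   fully-labelled growth protocol).
#' @inheritParams run_fixed_length
#' @return A `minde_trajectory`; recorded times start at the onset of
#'   growth.
#' @export
run_growing <- function(L0, L1, growth_rate, rates, config = sim_config(),
                        totals = min_totals()) {
  if (L1 <= L0) stop("final length must exceed starting length")
  if (growth_rate <= 0) stop("growth rate must be positive")
  # size the cell count for the final length, so the grid only stretches
  # (never remeshes) as the cell grows
  grid <- discretize(cell_geometry(L0), n_cells_for(config, L1))
  y <- initial_state(grid, totals, config$tilt)
  production <- if (is.null(config$production)) TRUE else config$production

  stage_model(rates, grid, production = production, totals = totals,
              tau = config$production_tau)
  if (config$burn_in > 0) {
    out <- integrate_staged(y, c(0, config$burn_in), config)
    y <- out[2, -1]
  }

  rec <- new_recorder()
  t_end <- (L1 - L0) / growth_rate
  pending <- seq(0, t_end, by = config$record_interval)
  dt_win <- max(config$record_interval, min(8, t_end / 10))
  t <- 0
  while (t < t_end - 1e-9) {
    t1 <- min(t + dt_win, t_end)
    L_cyl <- grid$geom$length - 2 * grid$geom$radius
    stage_model(rates, grid, dilution = growth_rate / L_cyl,
                production = production, totals = totals,
                tau = config$production_tau)
    targets <- pending[pending <= t1 + 1e-9]
    times <- sort(unique(c(0, targets - t, t1 - t)))
    out <- integrate_staged(y, times, config)
    y <- out[nrow(out), -1]
    keep <- keep_times(out[, 1] + t, targets)
    if (any(keep)) record_rows(rec, out[keep, , drop = FALSE], grid, t)
    pending <- pending[pending > t1 + 1e-9]
    grid <- grow(grid, t1 - t, growth_rate)
    t <- t1
  }
  finish_trajectory(rec, rates, config, totals, kind = "growing")
}

# which of `have` match a target time (tolerance for float round trips)
keep_times <- function(have, targets) {
  if (length(targets) == 0) return(rep(FALSE, length(have)))
  vapply(have, function(z) any(abs(z - targets) < 1e-6), logical(1))
}

#' Simulate a dividing cell
#'
#' The cell is held at fixed length while a septal constriction develops at
#' midcell following `schedule`: burn-in at the resting shape, then the
#' septum radius ramps linearly to its floor and the maximally constricted
#' shape is held.  On each geometry refresh the fields are remapped
#' conservatively (per-cell protein amounts are preserved as volumes and
#' areas change), so totals are conserved through constriction.
#'
#' @param L cell length, um.
#' @param schedule a [constriction_schedule()].
#' @inheritParams run_fixed_length
#' @return A `minde_trajectory`; recorded times start at zero, with
#'   constriction beginning at `schedule$t_start`.
#' @export
run_division <- function(L, rates, schedule = constriction_schedule(),
                         config = sim_config(duration = 900),
                         totals = min_totals()) {
  n_cells <- n_cells_for(config, L)
  grid <- discretize(cell_geometry(L), n_cells)
  y <- initial_state(grid, totals, config$tilt)
  production <- isTRUE(config$production)
  stage_model(rates, grid, production = production, totals = totals,
              tau = config$production_tau)
  if (config$burn_in > 0) {
    out <- integrate_staged(y, c(0, config$burn_in), config)
    y <- out[2, -1]
  }

  rec <- new_recorder()
  t_ramp0 <- schedule$t_start
  t_ramp1 <- schedule$t_start + schedule$ramp_duration
  dt_win <- 4
  pending <- seq(0, config$duration, by = config$record_interval)
  t <- 0
  while (t < config$duration - 1e-9) {
    in_ramp <- t >= t_ramp0 - 1e-9 && t < t_ramp1 - 1e-9
    t1 <- if (t < t_ramp0) min(t_ramp0, config$duration)
          else if (in_ramp) min(t + dt_win, t_ramp1, config$duration)
          else config$duration
    targets <- pending[pending <= t1 + 1e-9]
    times <- sort(unique(c(0, targets - t, t1 - t)))
    out <- integrate_staged(y, times, config)
    y <- out[nrow(out), -1]
    keep <- keep_times(out[, 1] + t, targets)
    if (any(keep)) record_rows(rec, out[keep, , drop = FALSE], grid, t)
    pending <- pending[pending > t1 + 1e-9]
    t <- t1
    if (t >= config$duration - 1e-9) break
    # refresh geometry to the septum radius at the new time
    r_now <- septum_radius_at(schedule, t, grid$geom$radius)
    if (r_now < grid$geom$radius - 1e-12) {
      con <- constriction(max(r_now, schedule$r_min_final),
                          schedule$concave_radius, schedule$convex_radius)
      geom_new <- cell_geometry(L, grid$geom$radius, con)
      grid_new <- build_grid(geom_new, grid$x_edges, grid$n_cap)
      y <- remap_conservative(y, grid, grid_new)
      grid <- grid_new
      stage_model(rates, grid, production = production, totals = totals,
                  tau = config$production_tau)
    }
  }
  finish_trajectory(rec, rates, config, totals, kind = "division",
                    schedule = schedule)
}

# preserve per-cell protein amounts across a change of volumes/areas on the
# same axial edges
remap_conservative <- function(y, grid_old, grid_new) {
  f <- matrix(y, 6, grid_old$n)
  f[1:2, ] <- f[1:2, ] * rep(grid_old$volume / grid_new$volume,
                             each = 2)
  f[3:6, ] <- f[3:6, ] * rep(grid_old$area / grid_new$area, each = 4)
  as.vector(f)
}

#' Total protein content of a state
#'
#' @param traj a `minde_trajectory`.
#' @return A [tibble::tibble] with per-snapshot MinD monomer-equivalent and
#'   MinE dimer-equivalent totals (molecule counts).
#' @export
protein_totals <- function(traj) {
  f <- traj$fields
  totD <- rowSums(f[, , "D"] * traj$volume) +
    rowSums((f[, , "d"] + 2 * f[, , "d2"] + 2 * f[, , "d2e2"]) * traj$area)
  totE <- rowSums(f[, , "E2"] * traj$volume) +
    rowSums((f[, , "e2"] + f[, , "d2e2"]) * traj$area)
  tibble::tibble(time = traj$times, minD = totD, minE_dimers = totE)
}

#' @export
print.minde_trajectory <- function(x, ...) {
  cat(sprintf("Min trajectory (%s): %d snapshots, %d cells, t = %g..%g s\n",
              x$kind, length(x$times), ncol(x$x), min(x$times),
              max(x$times)))
  cat(sprintf("  length %g..%g um, septum radius %g..%g um\n",
              min(x$length), max(x$length), min(x$septum_radius),
              max(x$septum_radius)))
  invisible(x)
}
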