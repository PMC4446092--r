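#' Collapse a trajectory to a kymograph
#'
#' Mimics the experimental reduction of a fluorescence image: the total MinD
#' signal is integrated over the cross-section perpendicular to the long
#' axis, giving monomer equivalents per um of axial length,
#' `(V D + A (d + 2 d2 + 2 d2e2)) / dx` per cell.  All MinD is counted
#' (partial labelling only scales the signal uniformly, which none of the
#' downstream analyses are sensitive to).
#'
#' @param traj a `minde_trajectory`.
#' @param channels also keep per-species per-um profiles (default FALSE).
#' @return An object of class `minde_kymograph`: `times`, `x` and `x_rel`
#'   (absolute and length-normalised cell-centre positions, time x cell
#'   matrices), `signal` (time x cell matrix), `dx`, `length`.
#' @export
collapse <- function(traj, channels = FALSE) {
  f <- traj$fields
  sig <- (f[, , "D"] * traj$volume +
            (f[, , "d"] + 2 * f[, , "d2"] + 2 * f[, , "d2e2"]) *
              traj$area) / traj$dx
  k <- list(times = traj$times, x = traj$x,
            x_rel = traj$x / traj$length, signal = sig, dx = traj$dx,
            length = traj$length, septum_radius = traj$septum_radius)
  if (channels) {
    per_um <- function(sp, w) f[, , sp] * w / traj$dx
    k$channels <- list(D = per_um("D", traj$volume),
                       E2 = per_um("E2", traj$volume),
                       d = per_um("d", traj$area),
                       d2 = per_um("d2", traj$area),
                       e2 = per_um("e2", traj$area),
                       d2e2 = per_um("d2e2", traj$area))
  }
  structure(k, class = "minde_kymograph")
}

# rows of the kymograph inside the analysis window (final fraction of the
# record by default)
window_rows <- function(k, window = NULL, window_frac = 0.6) {
  tt <- k$times
  if (is.null(window)) {
    t0 <- max(tt) - window_frac * (max(tt) - min(tt))
    which(tt >= t0 - 1e-9)
  } else {
    which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  }
}

# mean signal of the outer `frac` of the cell at each pole
pole_signals <- function(k, rows, frac = 0.1) {
  S <- k$signal[rows, , drop = FALSE]
  xr <- k$x_rel[rows, , drop = FALSE]
  lo <- xr <= frac; hi <- xr >= 1 - frac
  cbind(rowSums(S * lo) / pmax(rowSums(lo), 1),
        rowSums(S * hi) / pmax(rowSums(hi), 1))
}

#' Oscillation period of a kymograph
#'
#' Estimates the dominant Fourier period of the pole-region MinD signal (the
#' mean over the outer 10% of the cell at each pole), refined by parabolic
#' interpolation of the spectral peak.  For a pole-to-pole oscillation this
#' is the full cycle (both pole switches).  Returns `NA` when no significant
#' spectral peak stands out of the background, consistent with a stationary
#' pattern.
#'
#' @param k a `minde_kymograph` with uniformly spaced times.
#' @param window optional `c(t0, t1)` analysis window, s; default the final
#'   60% of the record (which should cover at least 3 cycles).
#' @param min_amplitude minimum relative temporal variation of the pole
#'   signal below which the pattern is treated as stationary.
#' @return Period in seconds, or `NA_real_`.
#' @export
estimate_period <- function(k, window = NULL, min_amplitude = 5e-3) {
  rows <- window_rows(k, window)
  if (length(rows) < 8) stop("analysis window too short")
  dt <- diff(k$times[rows])
  if (diff(range(dt)) > 1e-6) stop("kymograph times are not uniform")
  dt <- dt[1]
  ps <- pole_signals(k, rows)
  best <- NA_real_; best_pow <- -Inf
  for (j in 1:2) {
    s <- ps[, j]
    if (stats::sd(s) / mean(s) < min_amplitude) next
    s <- s - mean(s)
    nt <- length(s)
    pow <- Mod(stats::fft(s))^2
    # resolvable peaks only: at least 3 full cycles inside the window
    half <- 4:floor(nt / 2)
    pk <- half[which.max(pow[half])]
    # significance: dominant peak well above the median spectral level
    if (pow[pk] < 20 * stats::median(pow[half])) next
    # parabolic refinement on log power around the peak bin
    f <- (pk - 1) / (nt * dt)
    if (pk > 2 && pk < floor(nt / 2)) {
      lp <- log(pow[(pk - 1):(pk + 1)])
      den <- lp[1] - 2 * lp[2] + lp[3]
      delta <- if (abs(den) > 0) 0.5 * (lp[1] - lp[3]) / den else 0
      delta <- max(min(delta, 0.5), -0.5)
      f <- (pk - 1 + delta) / (nt * dt)
    }
    if (pow[pk] > best_pow) { best_pow <- pow[pk]; best <- 1 / f }
  }
  best
}

#' Thresholds of the pattern classifier
#'
#' The regime definitions are qualitative; these constants make them
#' operational and were fixed so that the classifier reproduces the known
#' regime assignments at reference lengths (e.g. a stationary polar pattern
#' at 2.45 um and a first-order breather at 3.5 um in the fully-labelled
#' system).
#'
#' @param stationary_cv temporal coefficient of variation below which a
#'   pattern counts as stationary at every position (default 0.05).
#' @param mode_ratio retained for reporting the first:second spatial
#'   cosine mode powers (default 2: within a factor 2 counts as mixed).
#' @param standing_threshold standing-wave index below which a mixed pattern
#'   counts as travelling (1 = pure standing wave).
#' @param central_frac width of the central window, as a fraction of cell
#'   length, that the detached high-MinD antinode must visit (default 0.4).
#' @param central_time_frac minimum fraction of the analysis window that the
#'   instantaneous high-MinD peak must spend inside the central window for
#'   the midcell-antinode call (default 0.2; a pole-to-pole breather scores
#'   essentially 0, an established midcell-antinode pattern 0.3-0.4).
#' @param node_var_frac relative temporal variance below which a position
#'   counts as a node (default 0.1).
#' @param window_frac final fraction of the record analysed (default 0.6).
#' @param pole_frac outer fraction of the cell used for pole signals.
#' @return A list of class `minde_pattern_control`.
#' @export
pattern_control <- function(stationary_cv = 0.05, mode_ratio = 2,
                            standing_threshold = 0.8, central_frac = 0.4,
                            central_time_frac = 0.2, node_var_frac = 0.1,
                            window_frac = 0.6, pole_frac = 0.1) {
  structure(list(stationary_cv = stationary_cv, mode_ratio = mode_ratio,
                 standing_threshold = standing_threshold,
                 central_frac = central_frac,
                 central_time_frac = central_time_frac,
                 node_var_frac = node_var_frac, window_frac = window_frac,
                 pole_frac = pole_frac),
            class = "minde_pattern_control")
}

#' Classify the patterning regime of a kymograph
#'
#' A pattern is stationary when the temporal coefficient of variation is
#' small at every position.  Otherwise the time-varying component is
#' projected onto the first two spatial cosine modes over the cell length:
#' one maximum-minimum pair (mode 1) is a first-order mode, two maxima or
#' two minima (mode 2) a second-order mode; when both modes carry comparable
#' power and the complex spatial phase at the dominant frequency drifts
#' (rather than flipping by pi at a node), the pattern is a travelling-wave
#' mixture.  A first-order oscillation in which the instantaneous high-MinD
#' peak detaches from the pole and spends a substantial part of each cycle
#' in the central region of the cell is a midcell antinode.
#'
#' @param k a `minde_kymograph`.
#' @param control a [pattern_control()].
#' @param window optional `c(t0, t1)` analysis window, s.
#' @return An object of class `minde_pattern_report` with fields `class`
#'   (one of `"stationary"`, `"first_order_breather"`,
#'   `"second_order_breather"`, `"mixed_travelling"`,
#'   `"midcell_antinode"`), `period` (s, `NA` if stationary),
#'   `node_positions`, `antinode_positions` (um), `oscillation_amplitude`
#'   (maximum temporal CV) and the mode powers.
#' @export
classify <- function(k, control = pattern_control(), window = NULL) {
  rows <- window_rows(k, window, control$window_frac)
  if (length(rows) < 16) stop("analysis window too short to classify")
  S <- k$signal[rows, , drop = FALSE]
  xr <- k$x_rel[rows[length(rows)], ]
  dx <- k$dx[rows[length(rows)], ]
  L <- mean(k$length[rows])

  m <- colMeans(S)
  sd_t <- apply(S, 2, stats::sd)
  cv <- sd_t / pmax(m, 0.1 * mean(m))
  amp <- max(cv)

  period <- estimate_period(k, window = range(k$times[rows]))

  if (amp < control$stationary_cv || is.na(period)) {
    rep_ <- list(class = "stationary", period = NA_real_,
                 node_positions = numeric(0),
                 antinode_positions = numeric(0),
                 oscillation_amplitude = amp,
                 mode_power = c(first = NA_real_, second = NA_real_),
                 standing_index = NA_real_, length = L)
    return(structure(rep_, class = "minde_pattern_report"))
  }

  FF <- sweep(S, 2, m)
  c1 <- as.vector(FF %*% (cos(pi * xr) * dx))
  c2 <- as.vector(FF %*% (cos(2 * pi * xr) * dx))
  P1 <- mean(c1^2); P2 <- mean(c2^2)

  # complex spatial amplitude at the dominant temporal frequency
  dt <- k$times[rows][2] - k$times[rows][1]
  nt <- nrow(FF)
  ft <- stats::mvfft(FF)
  pk <- which.max(rowSums(Mod(ft[2:floor(nt / 2), , drop = FALSE])^2)) + 1
  z <- ft[pk, ]
  standing <- Mod(sum(z^2 * dx)) / sum(Mod(z)^2 * dx)

  # variance antinodes/nodes
  v <- sd_t^2
  x_abs <- xr * L
  anti_idx <- which(diff(sign(diff(v))) < 0) + 1
  anti_idx <- anti_idx[v[anti_idx] > 0.5 * max(v)]
  if (v[1] > 0.5 * max(v) && v[1] > v[2]) anti_idx <- c(1, anti_idx)
  nn <- length(v)
  if (v[nn] > 0.5 * max(v) && v[nn] > v[nn - 1]) anti_idx <- c(anti_idx, nn)
  anti_idx <- merge_adjacent(anti_idx, v)
  node_idx <- which(diff(sign(diff(v))) > 0) + 1
  node_idx <- node_idx[v[node_idx] < control$node_var_frac * max(v)]
  node_idx <- merge_adjacent(node_idx, -v)

  # fraction of the window that the high-MinD peak spends detached from the
  # poles, inside the central part of the cell
  peak_rel <- xr[apply(S, 1, which.max)]
  half_w <- control$central_frac / 2
  frac_central <- mean(abs(peak_rel - 0.5) <= half_w)

  # breather modes are standing waves: a low standing index marks the
  # travelling-wave mode-mixing seen between the first- and second-order
  # regimes, whatever the mode balance
  cls <- if (standing < control$standing_threshold) {
    "mixed_travelling"
  } else if (P2 > P1) {
    "second_order_breather"
  } else if (frac_central >= control$central_time_frac) {
    "midcell_antinode"
  } else {
    "first_order_breather"
  }

  structure(list(class = cls, period = period,
                 node_positions = x_abs[node_idx],
                 antinode_positions = x_abs[anti_idx],
                 oscillation_amplitude = amp,
                 mode_power = c(first = P1, second = P2),
                 standing_index = standing,
                 central_peak_fraction = frac_central, length = L),
            class = "minde_pattern_report")
}

#' @export
print.minde_pattern_report <- function(x, ...) {
  cat("Min pattern report\n")
  cat(sprintf("  class: %s\n", x$class))
  cat(sprintf("  period: %s\n",
              if (is.na(x$period)) "none" else sprintf("%.1f s", x$period)))
  cat(sprintf("  oscillation amplitude (max temporal CV): %.3f\n",
              x$oscillation_amplitude))
  if (length(x$antinode_positions))
    cat("  antinodes (um):", sprintf("%.2f", x$antinode_positions), "\n")
  if (length(x$node_positions))
    cat("  nodes (um):", sprintf("%.2f", x$node_positions), "\n")
  invisible(x)
}

# plateau extrema can fire on two adjacent cells; keep the better one
merge_adjacent <- function(idx, v) {
  if (length(idx) < 2) return(idx)
  idx <- sort(idx)
  keep <- integer(0)
  run <- idx[1]
  for (i in idx[-1]) {
    if (i == run[length(run)] + 1) run <- c(run, i)
    else { keep <- c(keep, run[which.max(v[run])]); run <- i }
  }
  c(keep, run[which.max(v[run])])
}

# does a report match a class specifier used in bisection?
class_matches <- function(cls, spec) {
  spec <- match.arg(spec, c("stationary", "oscillating",
                            "first_order_breather", "second_order_breather",
                            "mixed_travelling", "midcell_antinode"))
  if (spec == "oscillating") cls != "stationary" else cls == spec
}

#' Locate a regime transition length by bisection
#'
#' Runs fixed-length simulations and classifies them, bisecting the cell
#' length at which the pattern switches from `from` to `to`.  The class
#' specifiers are the classifier classes plus `"oscillating"` (any
#' non-stationary class).  Lengths below/above the returned transition
#' classify as `from`/`to` by construction of the bisection.
#'
#' @param rates a [min_rates()] object.
#' @param from,to class specifiers bracketing the transition.
#' @param L_lo,L_hi bracketing lengths, um; classification must differ.
#' @param tol bisection tolerance on the length, um (default 0.1).
#' @param config a [sim_config()] used for every run.
#' @param totals a [min_totals()].
#' @param control a [pattern_control()].
#' @param verbose print each probe.
#' @return The transition length in um, with the probe history in attribute
#'   `"probes"`.
#' @export
find_transition <- function(rates, from, to, L_lo, L_hi, tol = 0.1,
                            config = sim_config(duration = 1000),
                            totals = min_totals(),
                            control = pattern_control(), verbose = FALSE) {
  probe <- function(L) {
    cls <- classify(collapse(run_fixed_length(L, rates, config, totals)),
                    control)$class
    if (verbose) message(sprintf("  L = %.3f um -> %s", L, cls))
    cls
  }
  c_lo <- probe(L_lo); c_hi <- probe(L_hi)
  if (!class_matches(c_lo, from))
    stop(sprintf("lower bracket %.2f um classifies as %s, not %s",
                 L_lo, c_lo, from))
  if (!class_matches(c_hi, to))
    stop(sprintf("upper bracket %.2f um classifies as %s, not %s",
                 L_hi, c_hi, to))
  probes <- data.frame(L = c(L_lo, L_hi), class = c(c_lo, c_hi))
  while (L_hi - L_lo > tol) {
    Lm <- (L_lo + L_hi) / 2
    cm <- probe(Lm)
    probes <- rbind(probes, data.frame(L = Lm, class = cm))
    if (class_matches(cm, to)) L_hi <- Lm else L_lo <- Lm
  }
  structure((L_lo + L_hi) / 2, probes = probes)
}

#' Midcell-node robustness criterion
#'
#' The parameter-robustness sweeps ask whether a 3.5 um cell still maintains
#' a definite node at midcell: the pattern must be a first-order breather
#' and the temporal variance at the cell centre must stay below a tenth of
#' the maximum temporal variance.
#'
#' @param k a `minde_kymograph` from a fixed-length 3.5 um run.
#' @param control a [pattern_control()].
#' @return `TRUE` or `FALSE`.
#' @export
midcell_node_check <- function(k, control = pattern_control()) {
  rep_ <- classify(k, control)
  if (rep_$class != "first_order_breather") return(FALSE)
  rows <- window_rows(k, NULL, control$window_frac)
  S <- k$signal[rows, , drop = FALSE]
  v <- apply(S, 2, stats::var)
  xr <- k$x_rel[rows[1], ]
  v_mid <- v[which.min(abs(xr - 0.5))]
  v_mid < control$node_var_frac * max(v)
}

#' Sweep one rate constant against the midcell-node criterion
#'
#' @param rates baseline [min_rates()].
#' @param name rate constant to vary.
#' @param values values to test.
#' @param L cell length, um (default 3.5, the robustness-sweep length).
#' @param config a [sim_config()].
#' @param totals a [min_totals()].
#' @return A [tibble::tibble] with the tested value, resulting class and
#'   whether the midcell node was maintained.
#' @export
sweep_parameter <- function(rates, name, values, L = 3.5,
                            config = sim_config(duration = 600),
                            totals = min_totals()) {
  stopifnot(name %in% names(rates))
  rows <- lapply(values, function(v) {
    r <- rates; r[[name]] <- v
    k <- collapse(run_fixed_length(L, r, config, totals))
    tibble::tibble(value = v, class = classify(k)$class,
                   midcell_node = midcell_node_check(k))
  })
  do.call(rbind, rows)
}

#' Protein partitioning between the cell halves during division
#'
#' Computes, at each recorded time, the percentage of MinD monomer
#' equivalents and MinE dimer equivalents above the midcell septum plane,
#' and summary root-mean-square deviations over the late-division window
#' (from maximal constriction to the projected binary-fission time by
#' default).
#'
#' @param traj a `minde_trajectory` from [run_division()].
#' @param window optional `c(t0, t1)` for the RMS summaries, s.
#' @return A [tibble::tibble] of class `minde_partition` with columns
#'   `time`, `frac_minD_top`, `frac_minE_top` (percent); the RMS summary is
#'   in `attr(, "metrics")`: deviations of each protein from parity and the
#'   MinD-MinE difference, in percentage points.
#' @export
partition_metrics <- function(traj, window = NULL) {
  top <- traj$x > traj$length / 2   # time x cell logical
  f <- traj$fields
  amtD <- f[, , "D"] * traj$volume +
    (f[, , "d"] + 2 * f[, , "d2"] + 2 * f[, , "d2e2"]) * traj$area
  amtE <- f[, , "E2"] * traj$volume + (f[, , "e2"] + f[, , "d2e2"]) *
    traj$area
  fracD <- 100 * rowSums(amtD * top) / rowSums(amtD)
  fracE <- 100 * rowSums(amtE * top) / rowSums(amtE)

  if (is.null(window)) {
    window <- if (!is.null(traj$schedule)) {
      c(traj$schedule$t_start + traj$schedule$ramp_duration,
        fission_time(traj$schedule, traj$grid$geom$radius))
    } else range(traj$times)
  }
  sel <- traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9
  rms <- function(x) sqrt(mean(x^2))
  metrics <- list(
    rms_from_parity_minD = rms(fracD[sel] - 50),
    rms_from_parity_minE = rms(fracE[sel] - 50),
    rms_D_vs_E = rms(fracD[sel] - fracE[sel]),
    window = window)
  out <- tibble::tibble(time = traj$times, frac_minD_top = fracD,
                        frac_minE_top = fracE)
  attr(out, "metrics") <- metrics
  class(out) <- c("minde_partition", class(out))
  out
}
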