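#' Spherocylinder cell geometry
#'
#' An idealised rod-shaped cell: a cylinder of radius `radius` with
#' hemispherical end caps, optionally carrying a midcell septal constriction.
#' The axial coordinate x runs from pole tip (x = 0) to pole tip
#' (x = `length`).
#'
#' @param length total pole-to-pole length, um.  Must be at least twice the
#'   radius.
#' @param radius cylinder and cap radius, um (default 0.5).
#' @param constriction optional [constriction()] descriptor.
#' @return An object of class `minde_geometry`.
#' @export
#' @examples
#' g <- cell_geometry(3.5)
#' radius_profile(g, 3.5 / 2)  # 0.5 in the cylinder
cell_geometry <- function(length, radius = 0.5, constriction = NULL) {
  if (length < 2 * radius)
    stop("cell length must be at least twice the radius")
  if (!is.null(constriction)) {
    stopifnot(inherits(constriction, "minde_constriction"))
    if (constriction$r_min > radius)
      stop("constriction radius cannot exceed the cell radius")
    w <- constriction_half_width(constriction, radius)
    if (length - 2 * radius < 2 * w)
      stop("cylinder section too short to host the septal constriction")
  }
  structure(list(length = length, radius = radius,
                 constriction = constriction),
            class = "minde_geometry")
}

#' Septal constriction descriptor
#'
#' The pinch profile is built from two circular arcs that are concave with
#' respect to the cytoplasm (radius `concave_radius`, tangent to the cylinder
#' wall) joined smoothly by a small convex arc (radius `convex_radius`) whose
#' lowest point sets the septum radius `r_min`.  The tangency between the
#' arcs has the closed form (xm - x1)^2 = (Rc + rv)^2 - (r_min + rv - R + Rc)^2
#' for a pinch centred at xm.
#'
#' @param r_min minimum cytoplasmic radius at the pinch, um.  Floored at
#'   0.077 um, below which the perimeter-to-area coupling becomes singular.
#' @param concave_radius radius of the two concave arcs, um (default 0.5).
#' @param convex_radius radius of the joining convex arc, um (default 0.1).
#' @return An object of class `minde_constriction`.
#' @export
constriction <- function(r_min, concave_radius = 0.5, convex_radius = 0.1) {
  if (r_min < 0.077 - 1e-12)
    stop("septum radius below the 0.077 um numerical floor")
  structure(list(r_min = r_min, concave_radius = concave_radius,
                 convex_radius = convex_radius),
            class = "minde_constriction")
}

# half-width of the constriction zone along x
constriction_half_width <- function(con, radius) {
  Rc <- con$concave_radius; rv <- con$convex_radius
  h <- con$r_min + rv - radius + Rc   # vertical offset of arc centres
  sq <- (Rc + rv)^2 - h^2
  if (sq < 0) stop("inconsistent constriction arc radii")
  sqrt(sq)
}

# radius r(x) and the product r(x) r'(x) for a geometry; the product stays
# finite at the pole tips where r' alone diverges, and is what the surface
# quadrature needs (r sqrt(1 + r'^2) = sqrt(r^2 + (r r')^2)).
profile_pieces <- function(geom, x) {
  L <- geom$length; R <- geom$radius
  r <- numeric(length(x)); rrp <- numeric(length(x))
  if (any(x < -1e-9 | x > L + 1e-9))
    stop("axial position outside the cell")
  x <- pmin(pmax(x, 0), L)

  # default: caps + cylinder
  lo <- x < R; hi <- x > L - R
  mid <- !(lo | hi)
  r[mid] <- R; rrp[mid] <- 0
  u <- R - x[lo]
  r[lo] <- sqrt(pmax(R^2 - u^2, 0)); rrp[lo] <- u
  u <- x[hi] - (L - R)
  r[hi] <- sqrt(pmax(R^2 - u^2, 0)); rrp[hi] <- -u

  con <- geom$constriction
  if (!is.null(con) && con$r_min < R - 1e-12) {
    Rc <- con$concave_radius; rv <- con$convex_radius
    xm <- L / 2
    w <- constriction_half_width(con, R)
    h <- con$r_min + rv - R + Rc          # arc-centre offset, see constriction()
    # tangency point: at distance Rc from the concave centre along the
    # centre-to-centre line
    xt <- w * rv / (Rc + rv)              # |x - xm| of the tangency point
    inz <- abs(x - xm) < w & mid
    if (any(inz)) {
      dxm <- abs(x[inz] - xm)
      sgn <- sign(x[inz] - xm)
      rz <- numeric(sum(inz)); rrpz <- numeric(sum(inz))
      cc <- dxm >= xt                      # on a concave arc
      # concave arc centred at (xm -/+ w, R - Rc); r grows away from the pinch
      u <- w - dxm[cc]
      s <- sqrt(pmax(Rc^2 - u^2, 0))
      rz[cc] <- (R - Rc) + s
      rrpz[cc] <- rz[cc] * sgn[cc] * (u / s)
      # convex arc centred at (xm, r_min + rv)
      cv <- !cc
      u <- dxm[cv]
      s <- sqrt(pmax(rv^2 - u^2, 0))
      rz[cv] <- (con$r_min + rv) - s
      rrpz[cv] <- rz[cv] * sgn[cv] * (u / s)
      r[inz] <- rz; rrp[inz] <- rrpz
    }
  }
  list(r = r, rrp = rrp)
}

#' Local cell radius along the axis
#'
#' @param geom a [cell_geometry()].
#' @param x axial positions, um, in `[0, length]`.
#' @return Radii in um: 0 at the pole tips, `radius` in the open cylinder,
#'   dipping to the septum radius at midcell when constricted.
#' @export
radius_profile <- function(geom, x) profile_pieces(geom, x)$r

#' Septum constriction ratios
#'
#' @param geom a constricted [cell_geometry()].
#' @return A list with `radius_ratio_pct` (constricted over expanded septum
#'   radius, percent) and `area_ratio_pct` (ratio of cross-sectional areas,
#'   percent, the square of the former).
#' @export
#' @examples
#' g <- cell_geometry(5, constriction = constriction(0.077))
#' constriction_metrics(g)  # 15.4 % and 2.4 %
constriction_metrics <- function(geom) {
  if (is.null(geom$constriction)) stop("geometry has no constriction")
  rr <- geom$constriction$r_min / geom$radius
  list(radius_ratio_pct = 100 * rr, area_ratio_pct = 100 * rr^2)
}

# 5-point Gauss-Legendre nodes/weights on [0, 1]
.gl5 <- list(
  x = c(0.046910077030668, 0.230765344947158, 0.5,
        0.769234655052842, 0.953089922969332),
  w = c(0.118463442528095, 0.239314335249683, 0.284444444444444,
        0.239314335249683, 0.118463442528095))

# integrate f(x) over [a_i, b_i] per interval, vectorised
.segment_quad <- function(f, a, b) {
  out <- numeric(length(a))
  for (j in seq_along(.gl5$x)) {
    xj <- a + .gl5$x[j] * (b - a)
    out <- out + .gl5$w[j] * f(xj)
  }
  out * (b - a)
}

#' Finite-volume discretisation of a cell geometry
#'
#' Divides the axial extent into cells of near-uniform width, with fixed-width
#' cap sections (so that growth stretches only the cylindrical cells), and
#' computes per-cell cytosolic volumes, lateral membrane areas, and the edge
#' conductance factors used by the solver.  Cytosolic species diffuse through
#' the local cross-section pi r(x)^2; membrane species diffuse along the
#' surface arc, with metric ds/dx = sqrt(1 + r'(x)^2).
#'
#' @param geom a [cell_geometry()].
#' @param n_cells requested number of axial cells (at least 20).  The
#'   realised count (`grid$n`) may differ slightly so that the cap/cylinder
#'   boundaries and the midplane fall on cell edges.
#' @return An object of class `minde_grid`: cell edges and centres, `volume`
#'   (um^3), `area` (um^2), `perimeter_to_area` (um^-1), `arc_metric`
#'   (mean ds/dx per cell), cylinder-membership flags and edge conductances.
#' @export
#' @examples
#' gr <- discretize(cell_geometry(3), 60)
#' sum(gr$volume)  # close to pi 0.25 (3 - 1) + 4/3 pi 0.125
discretize <- function(geom, n_cells = 80) {
  if (n_cells < 20) stop("need at least 20 axial cells")
  L <- geom$length; R <- geom$radius
  dx_t <- L / n_cells
  n_cap <- max(4L, as.integer(round(R / dx_t)))
  n_cyl <- max(6L, 2L * as.integer(ceiling((L - 2 * R) / dx_t / 2)))
  edges <- c(seq(0, R, length.out = n_cap + 1),
             seq(R, L - R, length.out = n_cyl + 1)[-1],
             seq(L - R, L, length.out = n_cap + 1)[-1])
  build_grid(geom, edges, n_cap)
}

build_grid <- function(geom, edges, n_cap) {
  n <- length(edges) - 1L
  a <- edges[-length(edges)]; b <- edges[-1]
  mid <- 0.5 * (a + b)

  vol_f <- function(x) pi * profile_pieces(geom, x)$r^2
  area_f <- function(x) {
    p <- profile_pieces(geom, x)
    2 * pi * sqrt(p$r^2 + p$rrp^2)
  }
  metric_f <- function(x) {
    p <- profile_pieces(geom, x)
    sqrt(p$r^2 + p$rrp^2) / pmax(p$r, 1e-12)
  }

  volume <- .segment_quad(vol_f, a, b)
  area <- .segment_quad(area_f, a, b)
  if (any(volume <= 0) || any(area <= 0))
    stop("degenerate (zero-volume) cell in discretisation")

  # edge quantities for the interior faces
  xe <- edges[2:n]
  pe <- profile_pieces(geom, xe)
  a_edge <- pi * pe$r^2
  perim_edge <- 2 * pi * pe$r
  dx_c <- diff(mid)
  # arc length between neighbouring cell centres
  ds_c <- .segment_quad(metric_f, mid[-n], mid[-1])

  is_cyl <- mid > geom$radius & mid < geom$length - geom$radius

  structure(list(
    geom = geom, n = n, n_cap = n_cap,
    x_edges = edges, x_mid = mid, dx = b - a,
    volume = volume, area = area,
    perimeter_to_area = area / volume,
    arc_metric = .segment_quad(metric_f, a, b) / (b - a),
    cond_cyt = a_edge / dx_c,
    cond_mem = perim_edge / ds_c,
    is_cylinder = is_cyl), class = "minde_grid")
}

#' Stretch a growing cell
#'
#' Lengthens the cylindrical section by `growth_rate * dt` while keeping the
#' polar caps fixed, and rebuilds the finite-volume grid on the stretched
#' edges.  Cap cells keep their width; cylinder cells widen uniformly, so a
#' species field carried per cell rides along with its cell (the solver's
#' dilution term accounts for the implied inflation of totals).  Growth is
#' additive: two consecutive calls equal one call with the summed time.
#'
#' @param grid a `minde_grid`.
#' @param dt time interval, s.
#' @param growth_rate elongation rate, um s^-1 (non-negative).
#' @return The stretched `minde_grid`.
#' @export
grow <- function(grid, dt, growth_rate) {
  if (growth_rate < 0) stop("growth rate must be non-negative")
  dL <- growth_rate * dt
  if (dL == 0) return(grid)
  geom <- grid$geom
  L0 <- geom$length; R <- geom$radius
  geom$length <- L0 + dL
  e <- grid$x_edges
  cyl <- e > R + 1e-12 & e < L0 - R - 1e-12
  scale <- (L0 + dL - 2 * R) / (L0 - 2 * R)
  e_new <- e
  e_new[cyl] <- R + (e[cyl] - R) * scale
  e_new[e >= L0 - R - 1e-12] <- e[e >= L0 - R - 1e-12] + dL
  build_grid(geom, e_new, grid$n_cap)
}

#' Export a geometry snapshot as a data frame
#'
#' @param grid a `minde_grid`.
#' @return A [tibble::tibble] with one row per cell: centre position, local
#'   radius, volume, membrane area and perimeter-to-area ratio.
#' @export
geometry_table <- function(grid) {
  tibble::tibble(
    x = grid$x_mid,
    radius = radius_profile(grid$geom, grid$x_mid),
    volume = grid$volume,
    area = grid$area,
    perimeter_to_area = grid$perimeter_to_area,
    cylinder = grid$is_cylinder)
}

#' Constriction schedule for division runs
#'
#' Linear ramp of the septum radius from the full cell radius down to
#' `r_min_final`, matching wild-type constriction kinetics, after which the
#' maximally constricted shape is held.
#'
#' @param t_start time at which constriction begins, s (default 300).
#' @param ramp_duration duration of the linear ramp, s (default 432).
#' @param r_min_final final septum radius, um (default 0.077, the numerical
#'   floor).
#' @param hold keep the final shape after the ramp (default TRUE).
#' @param concave_radius,convex_radius arc radii passed to [constriction()].
#' @return An object of class `minde_schedule`.
#' @export
constriction_schedule <- function(t_start = 300, ramp_duration = 432,
                                  r_min_final = 0.077, hold = TRUE,
                                  concave_radius = 0.5, convex_radius = 0.1) {
  structure(list(t_start = t_start, ramp_duration = ramp_duration,
                 r_min_final = r_min_final, hold = hold,
                 concave_radius = concave_radius,
                 convex_radius = convex_radius),
            class = "minde_schedule")
}

#' Septum radius at a time point
#'
#' @param schedule a [constriction_schedule()].
#' @param t time, s.
#' @param radius resting cell radius, um.
#' @return Septum radius in um under the linear ramp.
#' @export
septum_radius_at <- function(schedule, t, radius = 0.5) {
  frac <- pmin(pmax((t - schedule$t_start) / schedule$ramp_duration, 0), 1)
  if (!schedule$hold) frac <- ifelse(t > schedule$t_start +
                                       schedule$ramp_duration, 0, frac)
  radius + frac * (schedule$r_min_final - radius)
}

#' Projected binary-fission time
#'
#' Extrapolates the linear septum ramp to zero radius: the simulation halts
#' constriction at the numerical floor, but a real septum would keep closing
#' at the same rate.
#'
#' @inheritParams septum_radius_at
#' @return Time in s at which the extrapolated septum radius reaches zero.
#' @export
fission_time <- function(schedule, radius = 0.5) {
  rate <- (radius - schedule$r_min_final) / schedule$ramp_duration
  schedule$t_start + radius / rate
}
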