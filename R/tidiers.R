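#' Tidy a kymograph into long format
#'
#' @param x a `minde_kymograph`.
#' @param ... unused.
#' @return A [tibble::tibble] with one row per (time, cell): `time`, `x`,
#'   `x_rel`, `signal` (MinD monomer equivalents per um).
#' @export
tidy.minde_kymograph <- function(x, ...) {
  n <- ncol(x$signal)
  pos <- as.vector(x$x); rel <- as.vector(x$x_rel)
  sig <- as.vector(x$signal)
  tibble::tibble(
    time = rep(x$times, n),
    x = pos,
    x_rel = rel,
    signal = sig)
}

#' Tidy a trajectory into long format
#'
#' @param x a `minde_trajectory`.
#' @param ... unused.
#' @return A [tibble::tibble] with one row per (time, cell, species).
#' @export
tidy.minde_trajectory <- function(x, ...) {
  T_ <- length(x$times); n <- ncol(x$x)
  sp <- dimnames(x$fields)[[3]]
  pos <- rep(as.vector(x$x), 6)
  conc <- as.vector(x$fields)
  tibble::tibble(
    time = rep(x$times, n * 6),
    x = pos,
    species = rep(sp, each = T_ * n),
    concentration = conc)
}

#' One-row summary of a pattern report
#'
#' @param x a `minde_pattern_report`.
#' @param ... unused.
#' @return A one-row [tibble::tibble].
#' @export
glance.minde_pattern_report <- function(x, ...) {
  tibble::tibble(class = x$class, period = x$period,
                 oscillation_amplitude = x$oscillation_amplitude,
                 mode_power_first = x$mode_power[["first"]],
                 mode_power_second = x$mode_power[["second"]],
                 standing_index = x$standing_index,
                 n_nodes = length(x$node_positions),
                 n_antinodes = length(x$antinode_positions),
                 length = x$length)
}

#' One-row summary of a partition series
#'
#' @param x a `minde_partition`.
#' @param ... unused.
#' @return A one-row [tibble::tibble] with the RMS partition metrics (in
#'   percentage points) and the summary window.
#' @export
glance.minde_partition <- function(x, ...) {
  m <- attr(x, "metrics")
  tibble::tibble(rms_from_parity_minD = m$rms_from_parity_minD,
                 rms_from_parity_minE = m$rms_from_parity_minE,
                 rms_D_vs_E = m$rms_D_vs_E,
                 window_start = m$window[1], window_end = m$window[2])
}

#' Kymograph heat map
#'
#' Space-time heat map of the collapsed MinD signal in the conventional
#' colouring: high MinD yellow, low MinD dark blue.
#'
#' @param object a `minde_kymograph`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.minde_kymograph <- function(object, ...) {
  df <- tidy.minde_kymograph(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$x,
                                   fill = .data$signal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MinD / um") +
    ggplot2::labs(x = "time (s)", y = "axial position (um)") +
    ggplot2::theme_minimal()
}

#' Division partitioning plot
#'
#' Time course of the MinD and MinE percentages in the future top daughter
#' cell.
#'
#' @param object a `minde_partition`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.minde_partition <- function(object, ...) {
  df <- tibble::tibble(
    time = rep(object$time, 2),
    protein = rep(c("MinD", "MinE"), each = nrow(object)),
    frac_top = c(object$frac_minD_top, object$frac_minE_top))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frac_top,
                                   colour = .data$protein)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "% in top half") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
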