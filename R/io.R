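#' Persist a trajectory as a directory of plain-text arrays
#'
#' Writes the recorded fields (one CSV per species, times x cells), the
#' geometry arrays and a JSON metadata sidecar (`meta.json`: rates, totals,
#' configuration, kind, package version) into `dir`.  The layout is
#' self-describing and diff-friendly; [read_trajectory()] restores the
#' object.
#'
#' @param traj a `minde_trajectory`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, name)
    utils::write.csv(as.data.frame(m),
                     file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  for (sp in dimnames(traj$fields)[[3]])
    wr(traj$fields[, , sp], paste0("field_", sp))
  wr(traj$x, "x"); wr(traj$volume, "volume"); wr(traj$area, "area")
  wr(traj$dx, "dx")
  wr(data.frame(time = traj$times, length = traj$length,
                septum_radius = traj$septum_radius), "time_axis")
  meta <- list(kind = traj$kind, rates = unclass(traj$rates),
               totals = unclass(traj$totals),
               config = unclass(traj$config),
               schedule = if (!is.null(traj$schedule))
                 unclass(traj$schedule),
               n_cells = ncol(traj$x),
               package_version = as.character(utils::packageVersion("minde")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  rd <- function(name)
    as.matrix(utils::read.csv(file.path(dir, paste0(name, ".csv"))))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ta <- utils::read.csv(file.path(dir, "time_axis.csv"))
  sp <- .species
  T_ <- nrow(ta); n <- meta$n_cells
  arr <- array(NA_real_, c(T_, n, 6), dimnames = list(NULL, NULL, sp))
  for (s in sp) arr[, , s] <- rd(paste0("field_", s))
  structure(list(times = ta$time, fields = arr, x = rd("x"),
                 volume = rd("volume"), area = rd("area"), dx = rd("dx"),
                 length = ta$length, septum_radius = ta$septum_radius,
                 grid = NULL,
                 rates = do.call(min_rates, as.list(meta$rates)),
                 config = do.call(sim_config, as.list(meta$config)),
                 totals = do.call(min_totals, as.list(meta$totals)),
                 kind = meta$kind,
                 schedule = if (!is.null(meta$schedule))
                   do.call(constriction_schedule, as.list(meta$schedule))),
            class = "minde_trajectory")
}

#' Write a kymograph as CSV
#'
#' Times in rows, axial cells in columns; the first column holds the time
#' stamp and the header row the (final-snapshot) axial positions.
#'
#' @param k a `minde_kymograph`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(k, path) {
  m <- as.data.frame(k$signal)
  names(m) <- sprintf("x_%.4f", k$x[nrow(k$x), ])
  utils::write.csv(cbind(time = k$times, m), path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A small JSON document sufficient to re-run a scenario bit-compatibly:
#' scenario name, rates, totals, configuration, schedule/geometry, a hash of
#' the configuration, and the package version.
#'
#' @param scenario scenario name.
#' @param rates,totals,config,schedule the run inputs.
#' @param outputs named list of output paths.
#' @param path optional file to write the manifest to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(scenario, rates, totals = min_totals(),
                         config = sim_config(), schedule = NULL,
                         outputs = list(), path = NULL) {
  payload <- list(scenario = scenario, rates = unclass(rates),
                  totals = unclass(totals), config = unclass(config),
                  schedule = if (!is.null(schedule)) unclass(schedule),
                  outputs = outputs,
                  package_version =
                    as.character(utils::packageVersion("minde")))
  ser <- serialize(payload[c("scenario", "rates", "totals", "config",
                             "schedule")], NULL, ascii = TRUE)
  payload$config_hash <- sprintf("%08x",
                                 sum(as.double(ser) * seq_along(ser)) %%
                                   2^31)
  if (!is.null(path)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    return(invisible(payload))
  }
  payload
}
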