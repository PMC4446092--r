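#' Rate constants of the Min reaction-diffusion model
#'
#' Constructs the set of nine rate and diffusion constants that drive the
#' six-species MinD/MinE membrane-cytosol reaction network.  Defaults are the
#' fully-labelled preset (see [min_preset()]).  All reaction back-rates are
#' fixed at zero and all cytosolic MinD is treated as the active,
#' ATP-bound form, so no further kinetic fields exist.
#'
#' @param omega_db MinD membrane binding rate, um s^-1.
#' @param omega_edf MinD-MinE complex formation rate, um^2 s^-1.  The same
#'   constant governs the reaction of membrane MinE dimers with membrane MinD
#'   monomers (which ejects the monomer to the cytosol) and with membrane MinD
#'   dimers (which forms the heterotetramer).
#' @param omega_dim MinD dimerisation rate on the membrane, um^2 s^-1.
#' @param omega_hydr combined ATPase + heterotetramer dissociation rate, s^-1.
#' @param omega_eb MinE membrane binding rate, um s^-1.
#' @param omega_er MinE membrane release rate, s^-1.
#' @param D_D cytosolic MinD diffusion coefficient, um^2 s^-1.
#' @param D_E cytosolic MinE diffusion coefficient, um^2 s^-1.
#' @param D_m base membrane diffusion coefficient, um^2 s^-1.  Membrane
#'   species diffuse at 1, 1/2, 1/2 and 1/4 times `D_m` for the MinD monomer,
#'   MinD dimer, MinE dimer and heterotetramer respectively (the inverse of
#'   the number of membrane targeting sequences in each complex).
#' @return An object of class `minde_rates` (a named list of the nine
#'   constants).
#' @seealso [min_preset()], [min_totals()], [boltzmann_scaled_hydr()]
#' @export
#' @examples
#' p <- min_rates()                      # fully-labelled defaults
#' p_slow <- min_rates(omega_hydr = 0.075)
min_rates <- function(omega_db = 4, omega_edf = 22, omega_dim = 0.002,
                      omega_hydr = 0.12, omega_eb = 0.07, omega_er = 30,
                      D_D = 16, D_E = 20, D_m = 0.1) {
  p <- list(omega_db = omega_db, omega_edf = omega_edf,
            omega_dim = omega_dim, omega_hydr = omega_hydr,
            omega_eb = omega_eb, omega_er = omega_er,
            D_D = D_D, D_E = D_E, D_m = D_m)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate and diffusion constants must be finite and non-negative")
  structure(p, class = "minde_rates")
}

#' Named parameter presets
#'
#' Returns the rate constants for the two labelling regimes.  The presets
#' differ only in the ATPase/heterotetramer-dissociation rate (0.12 s^-1
#' fully labelled, 0.5 s^-1 partially labelled) and in the cytosolic MinD
#' diffusion coefficient (16 vs 24 um^2 s^-1): GFP fused to every MinD copy
#' slows both the dissociation step and cytosolic diffusion.
#'
#' @param name `"fully_labelled"` or `"partially_labelled"`.
#' @return A `minde_rates` object.
#' @export
#' @examples
#' min_preset("partially_labelled")$omega_hydr  # 0.5
min_preset <- function(name = c("fully_labelled", "partially_labelled")) {
  name <- match.arg(name)
  switch(name,
    fully_labelled = min_rates(),
    partially_labelled = min_rates(omega_hydr = 0.5, D_D = 24))
}

#' Total Min protein concentrations
#'
#' Cell-mean concentrations held constant over the cell cycle (protein
#' synthesis and degradation are not resolved).  MinE is counted in
#' homodimers; the monomer total is twice the dimer total.
#'
#' @param minD_total mean MinD monomer concentration, um^-3 (default 1389,
#'   i.e. 2.3 uM).
#' @param minE_dimer_total mean MinE homodimer concentration, um^-3 (default
#'   486, i.e. 972 um^-3 of monomers or 0.8 uM of dimers).
#' @return An object of class `minde_totals`.
#' @export
min_totals <- function(minD_total = 1389, minE_dimer_total = 486) {
  if (minD_total <= 0 || minE_dimer_total <= 0)
    stop("total concentrations must be positive")
  structure(list(minD_total = minD_total,
                 minE_dimer_total = minE_dimer_total),
            class = "minde_totals")
}

#' @export
print.minde_rates <- function(x, ...) {
  cat("Min model rate constants:\n")
  u <- c(omega_db = "um/s", omega_edf = "um^2/s", omega_dim = "um^2/s",
         omega_hydr = "1/s", omega_eb = "um/s", omega_er = "1/s",
         D_D = "um^2/s", D_E = "um^2/s", D_m = "um^2/s")
  for (nm in names(x))
    cat(sprintf("  %-10s %8g %s\n", nm, x[[nm]], u[[nm]]))
  invisible(x)
}

#' Write or read rate presets as YAML
#'
#' The schema mirrors the parameter names and units of [min_rates()]; total
#' concentrations are carried alongside when given.
#'
#' @param rates a `minde_rates` object.
#' @param path file path.
#' @param totals optional `minde_totals` to embed.
#' @return `write_rates_yaml()` returns `path` invisibly; `read_rates_yaml()`
#'   returns a list with elements `rates` and (possibly `NULL`) `totals`.
#' @export
write_rates_yaml <- function(rates, path, totals = NULL) {
  stopifnot(inherits(rates, "minde_rates"))
  obj <- list(rates = unclass(rates))
  if (!is.null(totals)) obj$totals <- unclass(totals)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_rates_yaml
#' @export
read_rates_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$rates)) stop("YAML file has no 'rates' section")
  rates <- do.call(min_rates, obj$rates)
  totals <- if (!is.null(obj$totals)) do.call(min_totals, obj$totals)
  list(rates = rates, totals = totals)
}

#' Temperature scaling of the hydrolysis rate
#'
#' The rate-limiting ATPase/heterotetramer-dissociation step is scaled by a
#' Boltzmann factor exp(eps (T - T0) / (k T T0)) with activation energy eps
#' per mole and the molar gas constant k, so the factor is exactly 1 at the
#' reference temperature and increases with T for positive eps.
#'
#' @param epsilon activation energy, kcal mol^-1 (default 11.5, about the
#'   free energy of ATP hydrolysis).
#' @param T0 reference temperature, K (default 305.15 K = 32 C, the
#'   temperature of the partially-labelled experiments).
#' @return An object of class `minde_temperature_scaling`; the gas constant
#'   in kcal mol^-1 K^-1 is fixed.
#' @export
temperature_scaling <- function(epsilon = 11.5, T0 = 305.15) {
  structure(list(epsilon = epsilon, T0 = T0, k = 1.98720425864083e-3),
            class = "minde_temperature_scaling")
}

#' Hydrolysis rate at a given temperature
#'
#' @param rates a `minde_rates` object.
#' @param temperature absolute temperature, K.
#' @param scaling a [temperature_scaling()] object.
#' @return The scaled `omega_hydr` in s^-1.
#' @export
#' @examples
#' boltzmann_scaled_hydr(min_rates(), 305.15)  # 0.12 at the reference T
boltzmann_scaled_hydr <- function(rates, temperature,
                                  scaling = temperature_scaling()) {
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  fac <- exp(scaling$epsilon * (temperature - scaling$T0) /
               (scaling$k * temperature * scaling$T0))
  rates$omega_hydr * fac
}

#' Rescale a rate set to a temperature
#'
#' Convenience wrapper returning a full `minde_rates` object with
#' `omega_hydr` replaced by its Boltzmann-scaled value.
#'
#' @inheritParams boltzmann_scaled_hydr
#' @return A `minde_rates` object.
#' @export
rates_at_temperature <- function(rates, temperature,
                                 scaling = temperature_scaling()) {
  rates$omega_hydr <- boltzmann_scaled_hydr(rates, temperature, scaling)
  rates
}

#' Equilibrium MinE membrane partitioning without MinD
#'
#' In the absence of MinD the only MinE reactions are membrane binding
#' (omega_eb, um s^-1) and release (omega_er, s^-1).  Balancing the two under
#' a unit-length (1 um^-1) surface-to-volume convention gives the fraction of
#' MinE that stays cytoplasmic at equilibrium,
#' 1 / (1 + omega_eb / omega_er * 1 um^-1).
#'
#' @param rates a `minde_rates` object.
#' @return A list with `rate_ratio` (omega_er / omega_eb, um^-1; `Inf` when
#'   omega_eb is zero) and `cytoplasmic_fraction` (dimensionless, in (0, 1]).
#' @export
#' @examples
#' mine_equilibrium_partition(min_rates())  # ratio ~429, fraction ~0.9977
mine_equilibrium_partition <- function(rates) {
  if (rates$omega_eb == 0)
    return(list(rate_ratio = Inf, cytoplasmic_fraction = 1))
  list(rate_ratio = rates$omega_er / rates$omega_eb,
       cytoplasmic_fraction = 1 / (1 + rates$omega_eb / rates$omega_er))
}
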