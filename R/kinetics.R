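#' Pointwise state of the six Min species
#'
#' Concentrations at one axial location: cytosolic species per volume
#' (um^-3), membrane-bound species per area (um^-2).
#'
#' @param D cytosolic MinD.ATP monomer, um^-3.
#' @param E2 cytosolic MinE dimer, um^-3.
#' @param d membrane MinD monomer, um^-2.
#' @param d2 membrane MinD dimer, um^-2.
#' @param e2 membrane MinE dimer, um^-2.
#' @param d2e2 membrane MinDE heterotetramer, um^-2.
#' @return An object of class `minde_state` (named numeric vector).
#' @export
point_state <- function(D = 0, E2 = 0, d = 0, d2 = 0, e2 = 0, d2e2 = 0) {
  s <- c(D = D, E2 = E2, d = d, d2 = d2, e2 = e2, d2e2 = d2e2)
  if (any(!is.finite(s)) || any(s < 0))
    stop("species concentrations must be finite and non-negative")
  structure(s, class = "minde_state")
}

#' Membrane reaction derivatives
#'
#' The non-diffusive, non-exchange kinetics of the four membrane species:
#' MinD monomers dimerise (2 d -> d2 at omega_dim d^2, consuming two
#' monomers per dimer); membrane MinE dimers eject MinD monomers back to the
#' cytosol (omega_edf e2 d, MinE acting catalytically) and bind MinD dimers
#' into heterotetramers (omega_edf e2 d2); hydrolysis dissolves the
#' heterotetramer (omega_hydr d2e2), returning the MinE dimer to the membrane
#' and two MinD monomers to the cytosol.  Membrane binding of D and E2 and
#' the matching cytosolic releases are accounted in [exchange_fluxes()].
#'
#' @param state a [point_state()].
#' @param rates a [min_rates()] object.
#' @return Named numeric vector of time derivatives for `d`, `d2`, `e2`,
#'   `d2e2` in um^-2 s^-1.
#' @export
#' @examples
#' membrane_reaction_rates(point_state(d2 = 2, e2 = 1), min_rates())
membrane_reaction_rates <- function(state, rates) {
  s <- validate_state(state)
  dimer <- rates$omega_dim * s[["d"]]^2
  expel <- rates$omega_edf * s[["e2"]] * s[["d"]]
  tetra <- rates$omega_edf * s[["e2"]] * s[["d2"]]
  hydro <- rates$omega_hydr * s[["d2e2"]]
  c(d = rates$omega_db * s[["D"]] - 2 * dimer - expel,
    d2 = dimer - tetra,
    e2 = rates$omega_eb * s[["E2"]] - rates$omega_er * s[["e2"]] -
      tetra + hydro,
    d2e2 = tetra - hydro)
}

#' Membrane-cytosol exchange fluxes
#'
#' Surface fluxes through the membrane, per unit membrane area, with the
#' convention that positive values move protein from the membrane to the
#' cytosol.  Cytosolic MinD gains the ejected monomers (omega_edf e2 d) and
#' the two monomers released per hydrolysed heterotetramer (2 omega_hydr
#' d2e2) and loses membrane binding (omega_db D); cytosolic MinE dimers gain
#' membrane release (omega_er e2) and lose binding (omega_eb E2).  The
#' binding losses reappear with opposite sign in the `d` and `e2` derivatives
#' of [membrane_reaction_rates()].
#'
#' @inheritParams membrane_reaction_rates
#' @return Named numeric vector `c(D = , E2 = )` in um^-2 s^-1.
#' @export
#' @examples
#' exchange_fluxes(point_state(D = 1389), min_rates())  # net MinD binding
exchange_fluxes <- function(state, rates) {
  s <- validate_state(state)
  c(D = rates$omega_edf * s[["e2"]] * s[["d"]] +
      2 * rates$omega_hydr * s[["d2e2"]] - rates$omega_db * s[["D"]],
    E2 = rates$omega_er * s[["e2"]] - rates$omega_eb * s[["E2"]])
}

validate_state <- function(state) {
  s <- unclass(state)
  need <- c("D", "E2", "d", "d2", "e2", "d2e2")
  if (!all(need %in% names(s))) stop("state is missing species fields")
  if (any(!is.finite(s[need])) || any(s[need] < 0))
    stop("species concentrations must be finite and non-negative")
  s[need]
}

#' Monomer- and dimer-equivalent bookkeeping
#'
#' MinD is counted in monomer equivalents (D, d, and two per d2 and d2e2),
#' MinE in dimer equivalents (E2, e2, and one per d2e2).  Cytosolic species
#' weight by volume, membrane species by area, so these helpers take the
#' local volume-per-area to express both on a membrane-area basis.
#'
#' @param state a [point_state()] (or plain named vector/list).
#' @param volume_per_area local cytosol volume per membrane area, um.
#' @return Monomer (MinD) or dimer (MinE) equivalents per um^2 of membrane.
#' @export
mind_equivalents <- function(state, volume_per_area = 1) {
  s <- validate_state(state)
  s[["D"]] * volume_per_area + s[["d"]] + 2 * s[["d2"]] + 2 * s[["d2e2"]]
}

#' @rdname mind_equivalents
#' @export
mine_equivalents <- function(state, volume_per_area = 1) {
  s <- validate_state(state)
  s[["E2"]] * volume_per_area + s[["e2"]] + s[["d2e2"]]
}
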