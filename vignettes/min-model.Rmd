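---
title: "A deterministic model of Min protein patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic model of Min protein patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(minde)
```

## The model

The Min system positions the division site of *E. coli*: MinD and MinE
oscillate from pole to pole, and the time-averaged MinD minimum at midcell
marks where the septum may form.  `minde` simulates a six-species
deterministic reaction–diffusion model of this system in which membrane
binding followed by on-membrane dimerisation of MinD supplies the two-step
nonlinearity that pattern formation requires.

The species are cytosolic MinD·ATP monomers (`D`, µm⁻³) and MinE dimers
(`E2`, µm⁻³), and four membrane-bound surface species (µm⁻²): MinD monomers
(`d`), MinD dimers (`d2`), MinE dimers (`e2`) and the MinDE heterotetramer
(`d2e2`).  The reactions, all irreversible (back-rates are zero by
construction), are:

* **MinD membrane binding** — `D → d` at rate `omega_db·D` (µm s⁻¹ times a
  volume concentration gives a surface flux).  All cytosolic MinD is treated
  as the active ATP-bound form; nucleotide exchange is not resolved.
* **MinD dimerisation** — `2d → d2` at `omega_dim·d²`; dimerisation is only
  possible on the membrane, which is the key cooperativity.
* **MinE membrane binding/release** — `E2 ↔ e2` at `omega_eb·E2` and
  `omega_er·e2`.  Release dominates binding by a factor of ~430 µm⁻¹, so in
  the absence of MinD well over 99% of MinE is cytoplasmic
  (`mine_equilibrium_partition()`).
* **Complex formation** — membrane MinE attacks MinD dimers,
  `e2 + d2 → d2e2` at `omega_edf·e2·d2`, and also ejects membrane MinD
  *monomers* back into the cytosol (`e2 + d → e2 + D`, same rate constant
  `omega_edf`; MinE acts catalytically and is not consumed).
* **Hydrolysis** — `d2e2 → E... → 2D + e2` at `omega_hydr·d2e2`: the
  combined ATPase and heterotetramer-dissociation step releases two MinD
  monomers to the cytosol and returns the MinE dimer to the membrane.

Membrane species diffuse at 1, ½, ½ and ¼ of the base membrane coefficient
`D_m` (`d`, `d2`, `e2`, `d2e2`), the inverse of the number of
membrane-targeting sequences each complex carries.

Two presets (`min_preset()`) encode the experimental labelling regimes.
They differ only in `omega_hydr` (0.12 s⁻¹ fully labelled vs 0.5 s⁻¹
partially labelled — GFP on every MinD copy stabilises the membrane dimer
and slows its dissociation about four-fold) and the cytosolic MinD
diffusion coefficient (16 vs 24 µm² s⁻¹).  Mean concentrations are 1389
MinD monomers and 486 MinE dimers per µm³ (`min_totals()`).

Temperature enters through a single Boltzmann factor on `omega_hydr`,
`exp(ε (T − T₀) / (k T T₀))` with ε = 11.5 kcal mol⁻¹ (about the free
energy of ATP hydrolysis), T₀ = 305.15 K and k the molar gas constant
(`boltzmann_scaled_hydr()`).  Hydrolysis is the rate-limiting step of the
cycle, so this one scaling reproduces the monotone decrease of the
oscillation period with temperature.

## Geometry and the 1D reduction

The cell is a spherocylinder of radius 0.5 µm.  Radially the cytosol is
taken as well mixed, so the model is reduced to one axial dimension: each
finite-volume cell `i` carries a cytosol volume `V_i` (from the local
cross-section `π r(x)²`) and a lateral membrane area `A_i` (from the
surface element `2π r √(1 + r′²) dx`).  Cytosolic species diffuse through
the cross-section; membrane species diffuse along the *arc length* of the
meridian, with metric `ds/dx = √(1 + r′²)` — the choice of projecting
membrane transport through the arc metric is this package's own, since a 1D
reduction must pick one.  Membrane–cytosol exchange converts surface fluxes
(µm⁻² s⁻¹) into volume rates through the local perimeter-to-area ratio
`A_i/V_i` (2/r = 4 µm⁻¹ in the open cylinder); no thin boundary shell is
needed in 1D.  No-flux conditions hold at both pole tips, where the
cross-section closes to zero by itself.

Septal constriction is modelled by an axial radius profile: two circular
arcs concave to the cytoplasm (radius 0.5 µm, tangent to the cylinder
wall) joined smoothly by a small convex arc (radius 0.1 µm) whose lowest
point is the septum radius.  The tangency condition has a closed form, so
the profile is exact at every ramp position.  The septum radius ramps
linearly from 0.5 µm to a floor of 0.077 µm (15.4% of the resting radius,
2.4% of the cross-sectional area) — below the floor the
perimeter-to-area coupling becomes singular — and the maximally
constricted shape is then held.  The default schedule starts the ramp at
300 s and completes it in 432 s, the wild-type constriction rate; linear
extrapolation of the ramp to zero radius defines a projected
binary-fission time (`fission_time()`, ≈ 811 s).

Growth stretches only the cylindrical section, linearly in time.  The grid
is Lagrangian: cap cells keep their width, cylinder cells widen, and every
species in the cylinder receives the growing-domain dilution term
`−(growth rate / cylinder length) · c`.  Homogeneous cytosolic production
of `D` and `E2` (a relaxation controller with a 1 s time constant acting on
the deficit between target and current totals) holds the cell-mean
concentrations constant; in practice they stay within 0.1% of target, well
inside the 1% the protocol requires.

## Numerical scheme

The semi-discrete system is integrated with `deSolve::lsode` (BDF, banded
Jacobian) using the package's compiled right-hand side.  With the state
ordered cell-major the Jacobian is banded with half-bandwidth 6 up to the
weak global production coupling, which the banded Newton iteration
tolerates.  A stiff implicit method is required: the complex-formation
term `omega_edf · e2 · d2` reaches effective rates of order 10⁴ s⁻¹ when
the polar MinD zone is loaded, far beyond what a practical explicit
reaction step could resolve.  Tolerances default to `rtol = atol = 1e-7`;
the finite-volume operators conserve protein exactly, and BDF preserves
these linear invariants, so totals drift only at round-off (≲ 10⁻¹³
relative over 1000 s, versus the 10⁻⁶ the design requires).  Default
resolution is one cell per 0.05 µm; doubling the resolution or tightening
the tolerances a hundred-fold changes the estimated oscillation period by
less than 0.1%.

Geometry changes (growth, constriction) are applied between short
integration windows — 8 s during growth (≤ 5 nm of elongation per window),
4 s during the constriction ramp (≤ 4 nm of septum radius) — with fields
remapped conservatively (per-cell amounts preserved) when volumes and
areas change.  Burn-in is 1000 s by default: the system is started from
homogeneous cytosolic distributions (`initial_state()`) and allowed to
converge to its attractor before recording.

The homogeneous initial state is exactly mirror-symmetric, and the
symmetric solution is dynamically unstable, so *which* pole wins would
otherwise be decided by accumulated round-off.  For reproducibility a
deterministic linear tilt of relative amplitude 10⁻³ is applied to the
initial cytosolic MinD field (pole-to-pole difference 0.2% of the mean,
volume-weighted mean unchanged).  Consequently the winning pole is fixed
by the tilt sign and is not physical.  With the tilt set to zero the
solver holds mirror symmetry at round-off level over short horizons
(≈10⁻¹³ relative at 100 s), but the instability amplifies round-off
exponentially, so symmetry is eventually lost in any floating-point
integration — the original model resolved this with numerical noise, and
the tilt simply makes the outcome reproducible.

## Pattern analysis

Trajectories are collapsed to kymographs exactly as fluorescence movies
are: total MinD (cytosolic plus membrane monomer equivalents) integrated
over the cross-section, per unit axial length.  Partial labelling only
scales this signal uniformly, so it needs no special handling.

The regime classifier operationalises qualitative definitions, and its
thresholds (exposed in `pattern_control()`) were fixed so that the
classifier reproduces the known regime assignments at reference lengths;
they are not fitted per run:

* **stationary** — temporal coefficient of variation below 5% at every
  position, or no resolvable spectral peak.
* **first/second order breather** — the time-varying signal is projected
  onto the first two axial cosine modes; the dominant mode gives the
  order.  Because breathers are standing waves, the call additionally
  requires a standing-wave index ≥ 0.8, where the index
  `|Σ z²| / Σ |z|²` over the complex spatial amplitude `z(x)` at the
  dominant frequency is 1 for a pure standing wave and 0 for a pure
  travelling wave.
* **mixed travelling** — a standing index below 0.8: the travelling-wave
  mode mixing observed between the first- and second-order regimes.
* **midcell antinode** — a mode-1-dominant oscillation whose
  instantaneous high-MinD peak spends at least 20% of the analysis window
  detached from the pole inside the central 40% of the cell.  In practice
  pole-to-pole breathers score ≈ 0 on this fraction and established
  midcell-antinode patterns 0.3–0.5, so the call is robust to the exact
  threshold.

Periods are estimated from the dominant discrete-Fourier component of the
pole-region signal (outer 10% of the cell at each pole), restricted to
components with at least three full cycles in the window and refined by
parabolic interpolation of the spectral peak; for a pole-to-pole
oscillation this fundamental is the full two-switch cycle.  Transition
lengths are located by bisection over fixed-length runs
(`find_transition()`, tolerance 0.1 µm), the same protocol used to fit
the model's free parameters originally.

Division runs are summarised by `partition_metrics()`: the fractions of
MinD and MinE monomer/dimer equivalents above the midcell plane over
time, and RMS deviations from parity over the window from maximal
constriction to the projected fission time.

## Problem sizes and runtimes

The package's tests and reproduction script use the default resolution
(0.05 µm cells, i.e. 50–130 cells for 2.2–6.5 µm cells), 1000 s burn-in
and 1000 s of recorded dynamics per fixed-length run, which covers 10–30
oscillation cycles depending on the regime; division runs record 900 s at
a 5 µm length.  A single fixed-length run takes on the order of a second
on one core, a transition bisection under a minute.

## Scope and limitations

* The model is deterministic.  Stochastic phase switching of stationary
  polar patterns in short cells — visible in fully-labelled experiments —
  cannot occur; the pattern simply stays at the pole the tilt selected.
* The 1D reduction reproduces transition lengths and periods well, but
  quantitative division statistics are sensitive to it.  In particular the
  relaxation to the symmetric state after septum closure proceeds through
  a slowly damped parity oscillation: protein fractions reach a few
  percent of parity one to two minutes after the constriction ramp ends,
  later than in the original axisymmetric treatment.  The settled end
  state is a symmetric stationary mode-2 pattern, with MinD accumulated at
  the poles rather than over the septum.
* MinC, FtsZ inhibition, nucleotide exchange kinetics, MinE conformational
  states and MinD-mediated MinE recruitment are all outside the model's
  topology.
* Parameters are taken as given; no fitting machinery is included.
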