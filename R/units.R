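#' Simulation unit system
#'
#' DPD is run in reduced units: the interaction cutoff \code{r_c} is the
#' length unit, the thermal energy \code{k_B T} the energy unit, and the
#' water-bead mass the mass unit.  The defaults follow the coarse-graining of
#' three water molecules per bead: a 3.23 Angstrom bead radius gives
#' \code{r_c = 6.46} Angstrom (one bead diameter), a 54 Da bead mass, and a
#' reduced liquid density of 3 beads per \code{r_c^3}.  Elapsed simulation
#' time is reported through a fixed mapping of physical picoseconds
#' represented per DPD step (3 ps by default).
#'
#' @param r_c Angstrom represented by one reduced length unit.
#' @param mass_da Daltons represented by one reduced mass unit.
#' @param ps_per_step Physical picoseconds represented per DPD step.
#' @param kT Reduced target temperature (energy unit; kept at 1).
#' @return An object of class \code{dpd_units}.
#' @examples
#' u <- sim_units()
#' angstrom_to_reduced(280, u)
#' @export
sim_units <- function(r_c = 6.46, mass_da = 54, ps_per_step = 3, kT = 1) {
  stopifnot(r_c > 0, mass_da > 0, ps_per_step > 0, kT > 0)
  u <- structure(
    list(r_c = r_c, mass_da = mass_da, ps_per_step = ps_per_step, kT = kT),
    class = "dpd_units")
  rho <- reduced_density(u)
  if (abs(rho - 3) > 0.1) {
    warning(sprintf(
      "unit system implies reduced water density %.3f, outside 3.0 +/- 0.1",
      rho))
  }
  u
}

#' Reduced bead number density implied by a unit system
#'
#' Bulk water at 1 g/cm^3 with \code{mass_da} daltons per bead gives the
#' number of beads per \code{r_c^3}; the default units yield 3.0, the
#' canonical DPD liquid density.
#'
#' @param units A \code{dpd_units} object.
#' @return Dimensionless bead density per \code{r_c^3}.
#' @export
reduced_density <- function(units = sim_units()) {
  avogadro <- 6.02214076e23
  per_A3 <- avogadro / units$mass_da * 1e-24  # beads per cubic Angstrom
  per_A3 * units$r_c^3
}

#' Convert Angstrom lengths to reduced units
#'
#' @param x Length(s) in Angstrom.
#' @param units A \code{dpd_units} object.
#' @return Length(s) in units of \code{r_c}.
#' @export
angstrom_to_reduced <- function(x, units = sim_units()) {
  x / units$r_c
}

#' Convert reduced lengths to Angstrom
#'
#' @inheritParams angstrom_to_reduced
#' @param x Length(s) in reduced units.
#' @export
reduced_to_angstrom <- function(x, units = sim_units()) {
  x * units$r_c
}

#' Number of DPD steps representing a physical duration
#'
#' With the default 3 ps-per-step mapping, 10 ns maps to 3334 steps.
#'
#' @param ns Duration in nanoseconds.
#' @param units A \code{dpd_units} object.
#' @return Integer step count (ceiling).
#' @export
ns_to_steps <- function(ns, units = sim_units()) {
  as.integer(ceiling(ns * 1000 / units$ps_per_step))
}

#' @export
print.dpd_units <- function(x, ...) {
  cat(sprintf(
    "DPD units: r_c = %.3f A, mass = %.1f Da, %.1f ps/step, kT = %g (rho = %.3f)\n",
    x$r_c, x$mass_da, x$ps_per_step, x$kT, reduced_density(x)))
  invisible(x)
}
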