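#' Simulation configuration (state) container
#'
#' Internal constructor assembling a \code{dpd_config}: positions and
#' velocities in reduced units, per-bead species / molecule id / molecule
#' name / reduced mass, a global bond list, the periodic box and the unit
#' system.  Positions are wrapped into [0, box).
#'
#' @keywords internal
new_config <- function(box, pos, vel, species, mol_id, mol_name, bonds,
                       units, seed, mass = NULL,
                       registry = default_bead_registry()) {
  if (is.null(mass)) mass <- bead_mass(species, registry) / units$mass_da
  pos <- wrap_positions(pos, box)
  cfg <- structure(
    list(box = box, pos = pos, vel = vel, species = species,
         mol_id = as.integer(mol_id), mol_name = mol_name, mass = mass,
         bonds = bonds, units = units, seed = seed),
    class = "dpd_config")
  cfg
}

wrap_positions <- function(pos, box) {
  for (d in 1:3) pos[, d] <- pos[, d] - box[d] * floor(pos[, d] / box[d])
  pos
}

#' Validate a configuration
#'
#' Checks the structural invariants: wrapped positions, bonds joining beads
#' of the same molecule, matching field lengths, (near-)zero total momentum.
#'
#' @param config A \code{dpd_config}.
#' @return The configuration, invisibly; stops on violation.
#' @export
validate_config <- function(config) {
  n <- nrow(config$pos)
  stopifnot(nrow(config$vel) == n, length(config$species) == n,
            length(config$mol_id) == n, length(config$mol_name) == n)
  for (d in 1:3) {
    if (any(config$pos[, d] < 0 | config$pos[, d] >= config$box[d])) {
      stop("positions not wrapped into [0, box)")
    }
  }
  b <- config$bonds
  if (nrow(b)) {
    if (any(b < 1) || any(b > n)) stop("bond index out of range")
    if (any(config$mol_id[b[, 1]] != config$mol_id[b[, 2]])) {
      stop("bond connects different molecules")
    }
  }
  invisible(config)
}

#' Number of beads in a configuration
#' @param config A \code{dpd_config}.
#' @export
n_beads <- function(config) nrow(config$pos)

#' Total momentum of a configuration
#'
#' @param config A \code{dpd_config}.
#' @return Length-3 vector of mass-weighted velocity sums (reduced units).
#' @export
total_momentum <- function(config) {
  colSums(config$vel * config$mass)
}

#' Instantaneous kinetic temperature
#'
#' 2 KE / (3N - 3) in reduced units (three degrees of freedom removed for
#' the conserved total momentum).
#'
#' @param config A \code{dpd_config}.
#' @export
kinetic_temperature <- function(config) {
  n <- n_beads(config)
  ke <- 0.5 * sum(config$mass * rowSums(config$vel^2))
  2 * ke / (3 * n - 3)
}

#' Molecule composition of a configuration
#'
#' @param config A \code{dpd_config}.
#' @return A data frame with one row per molecule kind and its count.
#' @export
molecule_counts <- function(config) {
  first <- !duplicated(config$mol_id)
  tab <- table(config$mol_name[first])
  data.frame(molecule = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' @export
print.dpd_config <- function(x, ...) {
  cat(sprintf(
    "DPD configuration: %d beads, %d molecules, %d bonds\n",
    n_beads(x), length(unique(x$mol_id)), nrow(x$bonds)))
  cat(sprintf("  box: %.2f x %.2f x %.2f r_c (%.0f x %.0f x %.0f A)\n",
              x$box[1], x$box[2], x$box[3],
              reduced_to_angstrom(x$box[1], x$units),
              reduced_to_angstrom(x$box[2], x$units),
              reduced_to_angstrom(x$box[3], x$units)))
  mc <- molecule_counts(x)
  cat("  composition:",
      paste(sprintf("%s=%d", mc$molecule, mc$count), collapse = ", "), "\n")
  invisible(x)
}

# Maxwell-Boltzmann velocities at kT with exact net-momentum removal.
init_velocities <- function(mass, kT = 1) {
  n <- length(mass)
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(kT / mass)), ncol = 3)
  p <- colSums(vel * mass)
  sweep(vel, 2, p / sum(mass))
}
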