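#' @title System builders for the three experiment geometries
#' @description
#' All builders fill space at the reduced liquid density rho = 3 beads per
#' r_c^3, grow chain molecules as random walks with bond length r_c/2 (soft
#' cores tolerate the resulting overlaps), draw velocities from the
#' Maxwell-Boltzmann distribution at kT = 1 and remove the net momentum
#' exactly.  Identical seeds give bit-identical configurations.
#' @name builders
NULL

RHO <- 3  # reduced liquid bead density

# grow one random-walk chain of n beads (bond length `bl`), optionally
# constrained to a region predicate; returns an n x 3 matrix (unwrapped)
grow_chain <- function(n, start, bl, accept = NULL, max_try = 200) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- start
  if (n == 1) return(pos)
  for (i in 2:n) {
    for (k in seq_len(max_try)) {
      dir <- stats::rnorm(3)
      cand <- pos[i - 1, ] + bl * dir / sqrt(sum(dir^2))
      if (is.null(accept) || accept(cand)) break
      if (k == max_try) cand <- pos[i - 1, ]  # give up: stack on predecessor
    }
    pos[i, ] <- cand
  }
  pos
}

# place a set of molecules; start points drawn by `draw_start`, beads
# constrained by `accept`.  Returns pos / species / mol_id / mol_name / bonds.
place_molecules <- function(counts, templates, draw_start, accept = NULL,
                            bl = 0.5, id0 = 0L) {
  pos <- list(); species <- list(); mol_id <- list(); mol_name <- list()
  bonds <- list()
  id <- id0
  offset <- 0L
  for (nm in names(counts)) {
    cnt <- counts[[nm]]
    if (cnt == 0) next
    tpl <- templates[[nm]]
    nb <- length(tpl$beads)
    for (m in seq_len(cnt)) {
      id <- id + 1L
      p <- grow_chain(nb, draw_start(), bl, accept)
      pos[[length(pos) + 1L]] <- p
      species[[length(species) + 1L]] <- tpl$beads
      mol_id[[length(mol_id) + 1L]] <- rep.int(id, nb)
      mol_name[[length(mol_name) + 1L]] <- rep.int(nm, nb)
      if (nrow(tpl$bonds)) {
        bonds[[length(bonds) + 1L]] <- tpl$bonds + offset
      }
      offset <- offset + nb
    }
  }
  list(pos = do.call(rbind, pos),
       species = unlist(species),
       mol_id = unlist(mol_id),
       mol_name = unlist(mol_name),
       bonds = if (length(bonds)) do.call(rbind, bonds)
               else matrix(integer(0), ncol = 2),
       next_id = id)
}

#' Random mixed box of solute and water
#'
#' Builds a periodic box filled to the reduced density rho = 3 in which the
#' solute : water molecule-count ratio equals \code{solute_pct} : 100 (the
#' concentration convention of the self-assembly experiments).
#'
#' @param box_A Box edge lengths in Angstrom (length 3, e.g.
#'   \code{c(280, 280, 280)}).
#' @param solute A \code{mol_template}, or \code{NULL} for pure water.
#' @param solute_pct Solute concentration, 0--100 (see \code{basis}).
#' @param seed Integer seed; same seed reproduces the configuration exactly.
#' @param units A \code{dpd_units} object.
#' @param registry A \code{bead_registry}.
#' @param basis How \code{solute_pct} is counted: \code{"molecule"} (default)
#'   makes the solute : water molecule-count ratio equal
#'   \code{solute_pct} : 100; \code{"bead"} makes \code{solute_pct} the
#'   percentage of all beads belonging to solute molecules (equivalently the
#'   solute volume fraction at uniform density).  The bead basis is the one
#'   under which an "X% solution" remains a solution in water for multi-bead
#'   solutes; a 30% molecule-ratio box of a 12-bead amphiphile would contain
#'   78% amphiphile beads and essentially no free water.
#' @return A \code{dpd_config}.
#' @examples
#' cfg <- random_mixed_box(c(52, 52, 52), build_template("Pam1CSK4"), 3, seed = 1)
#' molecule_counts(cfg)
#' @export
random_mixed_box <- function(box_A, solute = NULL, solute_pct = 0, seed = 1,
                             units = sim_units(),
                             registry = default_bead_registry(),
                             basis = c("molecule", "bead")) {
  basis <- match.arg(basis)
  if (solute_pct < 0 || solute_pct > 100) {
    stop("solute_pct must be between 0 and 100")
  }
  set.seed(seed)
  box <- angstrom_to_reduced(box_A, units)
  V <- prod(box)
  n_total <- round(RHO * V)
  nb_sol <- if (is.null(solute)) 0L else length(solute$beads)
  p <- solute_pct / 100
  if (basis == "bead" && nb_sol > 0 && p > 0) {
    # bead fraction f: B * n_s = f * n_total -> per-water-molecule ratio
    if (p >= 1) stop("bead-basis percentage must be below 100")
    p <- p / (1 - p) / nb_sol
  }
  n_w <- round(n_total / (1 + nb_sol * p))
  n_s <- round(p * n_w)
  if (solute_pct > 0 && n_s < 1) stop("box too small for one solute molecule")

  templates <- list(water = build_template("water", registry))
  counts <- list(water = n_w)
  if (n_s > 0) {
    templates[[solute$name]] <- solute
    counts[[solute$name]] <- n_s
  }
  draw <- function() stats::runif(3) * box
  pl <- place_molecules(counts, templates, draw)
  mass <- bead_mass(pl$species, registry) / units$mass_da
  vel <- init_velocities(mass, units$kT)
  cfg <- new_config(box, pl$pos, vel, pl$species, pl$mol_id, pl$mol_name,
                    pl$bonds, units, seed, mass = mass, registry = registry)
  validate_config(cfg)
}

#' Default droplet compositions
#'
#' Lipopeptide droplets use 201 water : 67 PLA : 1 Pam molecules; vitamin E
#' droplets use 750 water : 125 PLA : 117 vitamin E (an 8 percent w/w
#' vitamin E / PLA loading), each scalable by an integer factor.
#'
#' @param scale Integer multiplier applied to every count.
#' @param pam Which lipopeptide the Pam droplet carries.
#' @return Named count vector usable as \code{composition} in
#'   \code{\link{droplet_setup}}.
#' @export
pam_droplet_composition <- function(scale = 1,
                                    pam = c("Pam3CSK4", "Pam1CSK4")) {
  pam <- match.arg(pam)
  counts <- c(201, 67, 1) * scale
  names(counts) <- c("water", "PLA_70", pam)
  counts
}

#' @rdname pam_droplet_composition
#' @export
vitE_droplet_composition <- function(scale = 1) {
  c(water = 750, PLA_70 = 125, vitaminE = 117) * scale
}

#' Droplet nanoprecipitation setup
#'
#' Places the composition molecules uniformly inside a central sphere
#' (chains grown inside the sphere) and fills the remainder of the periodic
#' box with water at rho = 3.  The droplet interior is also filled at the
#' liquid density; the builder refuses compositions whose bead count would
#' compress the interior beyond 1.5 rho.
#'
#' @param box_A Box edge lengths in Angstrom.
#' @param droplet_radius_A Droplet radius in Angstrom (130 in the reference
#'   protocol).
#' @param composition Named molecule -> count vector (see
#'   \code{\link{pam_droplet_composition}}).
#' @param seed Integer seed.
#' @param units,registry As in \code{\link{random_mixed_box}}.
#' @param templates Optional named list of \code{mol_template}s covering the
#'   composition (defaults to the shipped set).
#' @return A \code{dpd_config}.
#' @export
droplet_setup <- function(box_A, droplet_radius_A = 130, composition,
                          seed = 1, units = sim_units(),
                          registry = default_bead_registry(),
                          templates = default_templates(registry)) {
  set.seed(seed)
  box <- angstrom_to_reduced(box_A, units)
  rad <- angstrom_to_reduced(droplet_radius_A, units)
  if (2 * rad > min(box)) stop("droplet does not fit in box")
  if (any(composition < 0)) stop("composition counts must be >= 0")
  missing <- setdiff(names(composition), names(templates))
  if (length(missing)) stop("no template for: ", paste(missing, collapse = ", "))

  center <- box / 2
  v_sph <- 4 / 3 * pi * rad^3
  nb_comp <- sum(vapply(names(composition), function(nm) {
    composition[[nm]] * length(templates[[nm]]$beads)
  }, 0))
  if (nb_comp > 1.5 * RHO * v_sph) stop("droplet overfull")

  in_sphere <- function(x) sum((x - center)^2) < rad^2
  draw_in_sphere <- function() {
    repeat {
      x <- center + (stats::runif(3) * 2 - 1) * rad
      if (in_sphere(x)) return(x)
    }
  }
  pl <- place_molecules(as.list(composition), templates, draw_in_sphere,
                        accept = in_sphere)

  # exterior water at rho = 3
  n_out <- round(RHO * (prod(box) - v_sph))
  out_pos <- matrix(NA_real_, n_out, 3)
  got <- 0L
  while (got < n_out) {
    cand <- matrix(stats::runif(3 * (n_out - got)), ncol = 3) %*% diag(box)
    keep <- rowSums(sweep(cand, 2, center)^2) >= rad^2
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      take <- min(nrow(cand), n_out - got)
      out_pos[(got + 1):(got + take), ] <- cand[seq_len(take), ]
      got <- got + take
    }
  }
  n_in_mols <- pl$next_id
  pos <- rbind(pl$pos, out_pos)
  species <- c(pl$species, rep("W", n_out))
  mol_id <- c(pl$mol_id, n_in_mols + seq_len(n_out))
  mol_name <- c(pl$mol_name, rep("water", n_out))

  mass <- bead_mass(species, registry) / units$mass_da
  vel <- init_velocities(mass, units$kT)
  cfg <- new_config(box, pos, vel, species, mol_id, mol_name, pl$bonds,
                    units, seed, mass = mass, registry = registry)
  validate_config(cfg)
}

#' Slab saturation setup
#'
#' Fills the region [0, layer) along x with PLA chains at rho = 3 and the
#' remainder of the box with water plus randomly dispersed solute at the
#' stated solute : water molecule percentage; solute placement excludes the
#' slab interior at t = 0.
#'
#' @param box_A Box edge lengths in Angstrom (e.g. \code{c(500, 100, 100)}).
#' @param layer_A PLA layer thickness along x, Angstrom.
#' @param solute A \code{mol_template} (or \code{NULL}).
#' @param solute_pct Solute molecules per 100 water molecules.
#' @param seed Integer seed.
#' @param units,registry As in \code{\link{random_mixed_box}}.
#' @return A \code{dpd_config}.
#' @export
slab_setup <- function(box_A, layer_A = 100, solute = NULL, solute_pct = 0,
                       seed = 1, units = sim_units(),
                       registry = default_bead_registry()) {
  set.seed(seed)
  box <- angstrom_to_reduced(box_A, units)
  thick <- angstrom_to_reduced(layer_A, units)
  if (thick >= box[1]) stop("layer thickness must be below the box x-length")
  if (solute_pct < 0 || solute_pct > 100) {
    stop("solute_pct must be between 0 and 100")
  }

  pla <- build_template("PLA_70", registry)
  n_pla <- round(RHO * thick * box[2] * box[3] / length(pla$beads))
  in_slab <- function(x) x[1] >= 0 && x[1] < thick
  draw_slab <- function() c(stats::runif(1) * thick, stats::runif(2) * box[2:3])
  templates <- list(PLA_70 = pla, water = build_template("water", registry))
  pl <- place_molecules(list(PLA_70 = n_pla), templates, draw_slab,
                        accept = in_slab)

  # water region
  nb_sol <- if (is.null(solute)) 0L else length(solute$beads)
  p <- solute_pct / 100
  n_region <- round(RHO * (box[1] - thick) * box[2] * box[3])
  n_w <- round(n_region / (1 + nb_sol * p))
  n_s <- round(p * n_w)
  in_water <- function(x) x[1] >= thick & x[1] < box[1]
  draw_water <- function() {
    c(thick + stats::runif(1) * (box[1] - thick), stats::runif(2) * box[2:3])
  }
  counts <- list(water = n_w)
  if (n_s > 0) {
    templates[[solute$name]] <- solute
    counts[[solute$name]] <- n_s
  }
  pl2 <- place_molecules(counts, templates, draw_water, accept = in_water,
                         id0 = pl$next_id)

  pos <- rbind(pl$pos, pl2$pos)
  species <- c(pl$species, pl2$species)
  mol_id <- c(pl$mol_id, pl2$mol_id)
  mol_name <- c(pl$mol_name, pl2$mol_name)
  bonds <- rbind(pl$bonds, pl2$bonds + nrow(pl$pos))

  mass <- bead_mass(species, registry) / units$mass_da
  vel <- init_velocities(mass, units$kT)
  cfg <- new_config(box, pos, vel, species, mol_id, mol_name, bonds,
                    units, seed, mass = mass, registry = registry)
  validate_config(cfg)
}

#' Mass ratio between two composition members
#'
#' 100 x (count x molecular mass) of the numerator over the denominator;
#' the vitamin E droplet composition returns about 8 (percent w/w vitamin E
#' vs PLA).
#'
#' @param composition Named molecule -> count vector.
#' @param numerator,denominator Molecule names present in the composition.
#' @param registry A \code{bead_registry}.
#' @param templates Optional named template list.
#' @return Percentage (numeric).
#' @examples
#' mass_ratio(vitE_droplet_composition(), "vitaminE", "PLA_70")
#' @export
mass_ratio <- function(composition, numerator, denominator,
                       registry = default_bead_registry(),
                       templates = default_templates(registry)) {
  for (nm in c(numerator, denominator)) {
    if (!nm %in% names(composition)) stop("molecule not in composition: ", nm)
  }
  if (composition[[denominator]] == 0) stop("denominator count is zero")
  m_num <- composition[[numerator]] * molecule_mass(templates[[numerator]], registry)
  m_den <- composition[[denominator]] * molecule_mass(templates[[denominator]], registry)
  100 * m_num / m_den
}
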