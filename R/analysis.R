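#' @title Trajectory analysis: clusters, morphology, localization
#' @description
#' The observables of the study are operationalized as explicit estimators:
#' contact-distance connected components for cluster detection, the
#' sphere-equivalent gyration diameter for micelle size, gyration-tensor
#' aspect ratios for the sphere / wormlike morphology split, a half-maximum
#' radial density criterion for nanoparticle diameter, and contact-cutoff
#' membership for encapsulated fractions.  All estimators are minimum-image
#' consistent: centers of mass are computed with the circular (angle
#' average) method so results are invariant under periodic-image shifts.
#' @name analysis
NULL

# bead species treated as hydrophobic contact sites by default
HYDROPHOBIC_SPECIES <- c("F", "LA", "CHR", "C5")

#' Periodic-boundary center of mass
#'
#' Mass-weighted center computed per dimension through the circular mean:
#' each coordinate is mapped to an angle on [0, 2 pi), the mean resultant
#' angle is mapped back.  Immune to clusters straddling the box boundary.
#'
#' @param pos N x 3 positions (reduced units, wrapped).
#' @param box Box edges (reduced).
#' @param mass Optional weights (default uniform).
#' @return Length-3 center, inside [0, box).
#' @export
pbc_center_of_mass <- function(pos, box, mass = NULL) {
  if (is.null(mass)) mass <- rep(1, nrow(pos))
  w <- mass / sum(mass)
  out <- numeric(3)
  for (d in 1:3) {
    th <- pos[, d] / box[d] * 2 * pi
    ang <- atan2(sum(w * sin(th)), sum(w * cos(th)))
    if (ang < 0) ang <- ang + 2 * pi
    out[d] <- ang / (2 * pi) * box[d]
  }
  out
}

min_image_disp <- function(pos, center, box) {
  d <- sweep(pos, 2, center)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Detect molecular clusters by bead contact
#'
#' Two molecules are connected when any pair of their filtered beads lies
#' within \code{cutoff} (minimum image); clusters are the connected
#' components.  By default contact is defined on the hydrophobic bead
#' species (F, LA, CHR, C5) at a cutoff of one interaction range.
#'
#' @param config A \code{dpd_config}.
#' @param bead_filter Character vector of bead species defining contact.
#' @param cutoff Contact distance, reduced units (> 0).
#' @param molecules Optional molecule-id subset to restrict the search to.
#' @param min_contacts Minimum number of filtered bead pairs within the
#'   cutoff for two molecules to count as connected.  The default 1 ("any
#'   pair") is the plain contact graph.  In crowded systems single grazing
#'   contacts chain visually distinct aggregates together; requiring as many
#'   shared contacts as the amphiphile tail has beads (e.g. 5 for a 5-bead
#'   palmitoyl tail) keeps co-micellar molecules (whose buried tails touch
#'   many partners) connected while cutting surface-to-surface bridges.
#' @return A \code{dpd_clusters} object: list of molecule-id vectors (sorted
#'   by decreasing size) plus the method metadata.
#' @export
find_clusters <- function(config, bead_filter = HYDROPHOBIC_SPECIES,
                          cutoff = 1.0, molecules = NULL, min_contacts = 1) {
  if (!length(bead_filter)) stop("empty bead filter")
  if (cutoff <= 0) stop("cutoff must be positive")
  sel <- config$species %in% bead_filter
  if (!is.null(molecules)) sel <- sel & config$mol_id %in% molecules
  mols <- unique(config$mol_id[sel])
  if (!length(mols)) {
    return(structure(list(clusters = list(), method = "bead-distance",
                          cutoff = cutoff, bead_filter = bead_filter),
                     class = "dpd_clusters"))
  }
  pr <- cpp_pairs_within(config$pos[sel, , drop = FALSE], config$box, cutoff)
  mid <- config$mol_id[sel]
  mi <- mid[pr$i]; mj <- mid[pr$j]
  keep <- mi != mj
  pair_key <- cbind(pmin(mi[keep], mj[keep]), pmax(mi[keep], mj[keep]))
  if (min_contacts > 1 && nrow(pair_key)) {
    key <- paste(pair_key[, 1], pair_key[, 2])
    tab <- table(key)
    good <- names(tab)[tab >= min_contacts]
    parts <- strsplit(good, " ", fixed = TRUE)
    edges <- if (length(parts)) {
      t(vapply(parts, function(x) as.integer(x), integer(2)))
    } else matrix(integer(0), ncol = 2)
  } else {
    edges <- unique(pair_key)
  }
  comp <- union_find(mols, edges)
  cl <- split(mols, comp)
  cl <- cl[order(-lengths(cl))]
  names(cl) <- NULL
  structure(list(clusters = cl, method = "bead-distance", cutoff = cutoff,
                 bead_filter = bead_filter, min_contacts = min_contacts),
            class = "dpd_clusters")
}

# connected components over `nodes` given an edge matrix of node labels
union_find <- function(nodes, edges) {
  idx <- seq_along(nodes)
  names(idx) <- as.character(nodes)
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    ei <- idx[as.character(edges[, 1])]
    ej <- idx[as.character(edges[, 2])]
    for (k in seq_along(ei)) {
      ri <- find(ei[k]); rj <- find(ej[k])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_along(nodes), find, 0L)
}

#' @export
print.dpd_clusters <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf(
    "%d clusters (contact cutoff %.2f r_c on %s)\n", length(sz), x$cutoff,
    paste(x$bead_filter, collapse = "/")))
  if (length(sz)) {
    cat("  sizes:", paste(utils::head(sz, 10), collapse = ", "),
        if (length(sz) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Micelle census of a configuration
#'
#' Identifies self-assembled aggregates of an amphiphile and reports one row
#' per aggregate of at least \code{min_molecules} molecules: size,
#' sphere-equivalent diameter, morphology class, aspect ratio and (for
#' wormlike aggregates) the slab-equivalent thickness.  Aggregates are
#' tail-bead contact clusters; \code{min_contacts} defaults to the length of
#' the molecule's hydrophobic tail so that bridge contacts between distinct
#' micelles do not merge them (see \code{\link{find_clusters}}).
#'
#' @param config A \code{dpd_config}.
#' @param solute_kind Molecule name of the amphiphile (default: all
#'   non-water molecules).
#' @param cutoff Contact cutoff, reduced units.
#' @param min_contacts Contact multiplicity for co-membership; \code{NULL}
#'   uses the number of hydrophobic beads in one tail of the molecule
#'   (total hydrophobic beads / number of tails), floor 1.
#' @param min_molecules Smallest aggregate reported (micelle convention: 3).
#' @param aspect_threshold Sphere / wormlike split.
#' @return Data frame with columns \code{size}, \code{diameter_nm},
#'   \code{shape}, \code{aspect}, \code{thickness_nm}; the cluster list is
#'   attached as attribute \code{clusters}.
#' @export
micelle_census <- function(config, solute_kind = NULL, cutoff = 1.0,
                           min_contacts = NULL, min_molecules = 3,
                           aspect_threshold = 3) {
  mols <- if (is.null(solute_kind)) {
    unique(config$mol_id[config$mol_name != "water"])
  } else {
    unique(config$mol_id[config$mol_name == solute_kind])
  }
  if (!length(mols)) stop("no solute molecules")
  if (is.null(min_contacts)) {
    rows <- config$mol_id %in% mols
    phob <- sum(config$species[rows] %in% HYDROPHOBIC_SPECIES) /
      length(unique(config$mol_id[rows]))
    # one 5-bead tail segment, or the whole hydrophobe if smaller
    min_contacts <- max(1, min(5, floor(phob)))
  }
  cl <- find_clusters(config, cutoff = cutoff, molecules = mols,
                      min_contacts = min_contacts)
  keep <- cl$clusters[lengths(cl$clusters) >= min_molecules]
  out <- do.call(rbind, lapply(keep, function(cc) {
    dia <- cluster_diameter(config, cc)
    if (length(cc) >= 5) {
      sh <- shape_class(config, cc, aspect_threshold)
      th <- if (sh == "wormlike") {
        bilayer_thickness(config, cc, aspect_threshold)
      } else NA_real_
      data.frame(size = length(cc), diameter_nm = dia,
                 shape = as.character(sh), aspect = attr(sh, "aspect"),
                 thickness_nm = th)
    } else {
      data.frame(size = length(cc), diameter_nm = dia, shape = "sphere",
                 aspect = NA_real_, thickness_nm = NA_real_)
    }
  }))
  if (is.null(out)) {
    out <- data.frame(size = integer(0), diameter_nm = numeric(0),
                      shape = character(0), aspect = numeric(0),
                      thickness_nm = numeric(0))
  }
  structure(out, clusters = keep, min_contacts = min_contacts)
}

#' Molecule ids of the largest cluster
#' @param clusters A \code{dpd_clusters}.
#' @export
largest_cluster <- function(clusters) {
  if (!length(clusters$clusters)) stop("no clusters")
  clusters$clusters[[which.max(lengths(clusters$clusters))]]
}

cluster_bead_rows <- function(config, cluster, species_filter = NULL) {
  rows <- which(config$mol_id %in% cluster)
  if (!is.null(species_filter)) {
    rows <- rows[config$species[rows] %in% species_filter]
  }
  rows
}

# mass-weighted gyration tensor eigenvalues (decreasing) + Rg^2
gyration_eigen <- function(config, cluster) {
  rows <- cluster_bead_rows(config, cluster)
  pos <- config$pos[rows, , drop = FALSE]
  m <- config$mass[rows]
  ctr <- pbc_center_of_mass(pos, config$box, m)
  d <- min_image_disp(pos, ctr, config$box)
  w <- m / sum(m)
  gt <- crossprod(d * sqrt(w))  # sum_i w_i d_i d_i^T
  ev <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  list(lambda = pmax(ev, 0), rg2 = sum(pmax(ev, 0)), center = ctr)
}

#' Sphere-equivalent cluster diameter
#'
#' Mass-weighted radius of gyration of all beads in the cluster's molecules,
#' reported as the diameter of the uniform sphere with the same Rg:
#' D = 2 sqrt(5/3) Rg (a uniform ball of radius R has Rg^2 = 3/5 R^2).
#'
#' @param config A \code{dpd_config}.
#' @param cluster Vector of molecule ids.
#' @return Diameter in nanometres.
#' @export
cluster_diameter <- function(config, cluster) {
  if (!length(cluster)) stop("empty cluster")
  g <- gyration_eigen(config, cluster)
  2 * sqrt(5 / 3 * g$rg2) * config$units$r_c / 10
}

#' Sphere / wormlike morphology classification
#'
#' Classifies a cluster from its gyration-tensor eigenvalues
#' lambda1 >= lambda2 >= lambda3: wormlike (elongated or flattened) when the
#' aspect ratio sqrt(lambda1 / lambda3) exceeds the threshold, spherical
#' otherwise.  Degenerate (collinear or planar) bead sets are reported as
#' wormlike.
#'
#' @param config A \code{dpd_config}.
#' @param cluster Vector of molecule ids (>= 5 molecules).
#' @param aspect_threshold Classification threshold (default 3).
#' @return \code{"sphere"} or \code{"wormlike"}, with attributes
#'   \code{aspect} and \code{lambda}.
#' @export
shape_class <- function(config, cluster, aspect_threshold = 3) {
  if (length(cluster) < 5) stop("shape classification needs >= 5 molecules")
  g <- gyration_eigen(config, cluster)
  lam <- g$lambda
  if (lam[3] <= 1e-12) {
    aspect <- Inf
  } else {
    aspect <- sqrt(lam[1] / lam[3])
  }
  cls <- if (aspect > aspect_threshold) "wormlike" else "sphere"
  structure(cls, aspect = aspect, lambda = lam)
}

#' Slab-equivalent bilayer thickness of a wormlike cluster
#'
#' Full width along the smallest gyration-tensor axis, using the uniform
#' slab correspondence: a slab of half-thickness t has lambda3 = t^2 / 3, so
#' the full width is 2 sqrt(3 lambda3).
#'
#' @param config A \code{dpd_config}.
#' @param cluster Vector of molecule ids, classified wormlike.
#' @param aspect_threshold Passed to \code{\link{shape_class}}.
#' @return Thickness in nanometres.
#' @export
bilayer_thickness <- function(config, cluster, aspect_threshold = 3) {
  cls <- shape_class(config, cluster, aspect_threshold)
  if (cls == "sphere") {
    stop("cluster is sphere-class; classify with shape_class first")
  }
  lam3 <- attr(cls, "lambda")[3]
  2 * sqrt(3 * lam3) * config$units$r_c / 10
}

#' Local bilayer thickness of a branched or percolating aggregate
#'
#' \code{\link{bilayer_thickness}} assumes an isolated slab-like cluster; a
#' wormlike phase that has grown into a connected network has box-scale
#' gyration eigenvalues and needs a local measure.  This estimator samples
#' core (tail) beads of the aggregate, estimates the local sheet normal as
#' the smallest-variance direction of the surrounding core beads, projects
#' all aggregate beads inside a transverse cylinder onto that normal, and
#' reports the median over samples of the full width at half maximum of the
#' projected density (the same half-maximum convention as
#' \code{\link{particle_diameter}}).  On an isolated uniform slab it
#' recovers the slab width.
#'
#' @param config A \code{dpd_config}.
#' @param cluster Vector of molecule ids of the aggregate.
#' @param core_species Bead species defining the hydrophobic core (normal
#'   estimation and sampling points); default F.
#' @param window Radius (reduced) of the neighbourhood used for the normal.
#' @param transverse Radius (reduced) of the projection cylinder.
#' @param n_samples Number of sampled core beads.
#' @param span Half-range (reduced) of the projection axis.
#' @param seed Seed for the bead sampling.
#' @return Thickness in nanometres, with the per-sample widths in attribute
#'   \code{samples}.
#' @export
local_bilayer_thickness <- function(config, cluster, core_species = "F",
                                    window = 2.5, transverse = 1.5,
                                    n_samples = 200, span = 6,
                                    seed = 1) {
  rows <- cluster_bead_rows(config, cluster)
  pos <- config$pos[rows, , drop = FALSE]
  sp <- config$species[rows]
  core <- which(sp %in% core_species)
  if (length(core) < 30) stop("aggregate core too small")
  set.seed(seed)
  samp <- core[sample(length(core), min(n_samples, length(core)))]
  bw <- 0.25
  br <- seq(-span, span, bw)
  widths <- numeric(0)
  for (k in samp) {
    d <- min_image_disp(pos, pos[k, ], config$box)
    r2 <- rowSums(d^2)
    near_core <- which(r2 < window^2 & sp %in% core_species)
    if (length(near_core) < 20) next
    dc <- d[near_core, , drop = FALSE]
    gt <- crossprod(sweep(dc, 2, colMeans(dc))) / length(near_core)
    nrm <- eigen(gt, symmetric = TRUE)$vectors[, 3]
    z <- drop(d %*% nrm)
    sel <- which(r2 - z^2 < transverse^2 & abs(z) < span)
    if (length(sel) < 20) next
    dens <- graphics::hist(z[sel], breaks = br, plot = FALSE)$counts
    mid <- (br[-1] + br[-length(br)]) / 2
    # core plateau around the sampled bead, half-crossing by interpolation
    plateau <- mean(dens[abs(mid) < 0.5])
    if (!is.finite(plateau) || plateau <= 0) next
    half <- plateau / 2
    cross_out <- function(idx_seq) {
      prev <- NULL
      for (i in idx_seq) {
        if (dens[i] < half) {
          if (is.null(prev)) return(abs(mid[i]))
          f <- (dens[prev] - half) / (dens[prev] - dens[i])
          return(abs(mid[prev] + f * (mid[i] - mid[prev])))
        }
        prev <- i
      }
      span
    }
    i0 <- which.min(abs(mid))
    widths <- c(widths,
                cross_out(seq(i0, length(dens))) + cross_out(seq(i0, 1)))
  }
  if (!length(widths)) stop("no valid local samples")
  structure(stats::median(widths) * config$units$r_c / 10, samples = widths)
}

#' Nanoparticle diameter from the radial density half-maximum
#'
#' Builds the radial number-density profile of the cluster's LA beads about
#' the cluster center of mass and returns twice the radius at which the
#' density first falls to half the core plateau (linear interpolation
#' between bins).  Clusters with fewer than 100 profile beads fall back to
#' the sphere-equivalent gyration diameter, flagged through the
#' \code{fallback} attribute.
#'
#' @param config A \code{dpd_config}.
#' @param cluster Vector of molecule ids (the PLA particle).
#' @param species_filter Bead species forming the profile (default LA).
#' @param bin_width Radial bin width, reduced units.
#' @return Diameter in Angstrom (attribute \code{fallback} = TRUE when the
#'   gyration fallback was used).
#' @export
particle_diameter <- function(config, cluster, species_filter = "LA",
                              bin_width = 0.25) {
  if (!length(cluster)) stop("empty cluster")
  rows <- cluster_bead_rows(config, cluster, species_filter)
  if (length(rows) < 100) {
    d_nm <- cluster_diameter(config, cluster)
    return(structure(d_nm * 10, fallback = TRUE))
  }
  pos <- config$pos[rows, , drop = FALSE]
  m <- config$mass[rows]
  ctr <- pbc_center_of_mass(pos, config$box, m)
  r <- sqrt(rowSums(min_image_disp(pos, ctr, config$box)^2))
  r0 <- sqrt(5 / 3 * gyration_eigen(config, cluster)$rg2)  # scale estimate
  edges <- seq(0, max(r) + bin_width, by = bin_width)
  counts <- graphics::hist(r, breaks = edges, plot = FALSE)$counts
  vol <- 4 / 3 * pi * diff(edges^3)
  dens <- counts / vol
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  core <- dens[mid < 0.6 * r0]
  plateau <- if (length(core)) mean(core) else max(dens)
  half <- plateau / 2
  # scan outward from the core for the first crossing below half-max
  start <- max(1L, sum(mid < 0.5 * r0))
  cross <- NA_real_
  for (k in seq(start, length(dens))) {
    if (dens[k] < half) {
      if (k == 1) { cross <- mid[1]; break }
      f <- (dens[k - 1] - half) / (dens[k - 1] - dens[k])
      cross <- mid[k - 1] + f * (mid[k] - mid[k - 1])
      break
    }
  }
  if (is.na(cross)) cross <- max(r)
  structure(2 * cross * config$units$r_c, fallback = FALSE)
}

#' Nanoparticle diameter along a trajectory
#'
#' Tracks \code{\link{particle_diameter}} of the largest PLA cluster in each
#' snapshot; used to follow the contraction during nanoprecipitation.
#'
#' @param trajectory A \code{dpd_trajectory}.
#' @param cutoff Cluster contact cutoff.
#' @return Data frame with \code{step}, \code{time_ps}, \code{diameter_A}.
#' @export
particle_diameter_trace <- function(trajectory, cutoff = 1.0) {
  out <- vapply(trajectory$snapshots, function(cfg) {
    cl <- find_clusters(cfg, bead_filter = "LA", cutoff = cutoff)
    as.numeric(particle_diameter(cfg, largest_cluster(cl)))
  }, 0)
  data.frame(step = trajectory$scalars$step,
             time_ps = trajectory$scalars$time_ps, diameter_A = out)
}

#' Radial ordering of a molecule kind about a particle
#'
#' Mean radial distance from the particle center of mass for each bead
#' species of the given molecule kind.  For assembled lipopeptide particles
#' the hydrophilic lysine beads sit outside the fatty acid beads
#' (mean r(K) > mean r(F)); for buried hydrophobes all species sit below the
#' particle radius.
#'
#' @param config A \code{dpd_config}.
#' @param particle Vector of molecule ids defining the particle.
#' @param molecule_kind Molecule name whose beads are profiled.
#' @return Named vector of mean radial distances (reduced units), with the
#'   particle center as attribute.
#' @export
radial_ordering <- function(config, particle, molecule_kind) {
  if (!length(particle)) stop("empty particle")
  prow <- cluster_bead_rows(config, particle)
  ctr <- pbc_center_of_mass(config$pos[prow, , drop = FALSE], config$box,
                            config$mass[prow])
  rows <- which(config$mol_name == molecule_kind)
  if (!length(rows)) {
    return(structure(stats::setNames(numeric(0), character(0)), center = ctr))
  }
  r <- sqrt(rowSums(min_image_disp(config$pos[rows, , drop = FALSE], ctr,
                                   config$box)^2))
  out <- tapply(r, config$species[rows], mean)
  structure(as.vector(out), names = names(out), center = ctr)
}

#' Encapsulated fraction of a solute
#'
#' Labels every molecule of \code{solute_kind} as \code{inside} (any bead
#' within \code{cutoff} of an LA bead of the host), \code{micelle} (not
#' inside, and member of a solute-only contact cluster of at least
#' \code{micelle_min} molecules) or \code{free}, and reports the fractions.
#'
#' @param config A \code{dpd_config}.
#' @param host_region Vector of molecule ids of the PLA host (particle or
#'   slab), typically \code{largest_cluster(find_clusters(config, "LA"))}.
#' @param solute_kind Molecule name of the solute.
#' @param cutoff Contact cutoff, reduced units.
#' @param micelle_min Minimum solute-only cluster size counting as a micelle.
#' @return A \code{dpd_localization}: fractions, free count and per-molecule
#'   labels.
#' @export
encapsulated_fraction <- function(config, host_region, solute_kind,
                                  cutoff = 1.0, micelle_min = 3) {
  if (!length(host_region)) stop("no host region")
  host_rows <- cluster_bead_rows(config, host_region, "LA")
  if (!length(host_rows)) stop("host region has no LA beads")
  sol_rows <- which(config$mol_name == solute_kind)
  if (!length(sol_rows)) stop("no molecules of kind ", solute_kind)
  sol_mols <- unique(config$mol_id[sol_rows])

  # contact with the host: pair search over host LA beads + solute beads
  comb <- rbind(config$pos[host_rows, , drop = FALSE],
                config$pos[sol_rows, , drop = FALSE])
  nh <- length(host_rows)
  pr <- cpp_pairs_within(comb, config$box, cutoff)
  cross <- (pr$i <= nh) != (pr$j <= nh)
  sol_pair <- ifelse(pr$i[cross] > nh, pr$i[cross], pr$j[cross]) - nh
  inside_mols <- unique(config$mol_id[sol_rows[sol_pair]])

  labels <- stats::setNames(rep("free", length(sol_mols)),
                            as.character(sol_mols))
  labels[as.character(inside_mols)] <- "inside"

  # solute-only micelles among the not-inside molecules
  rest <- setdiff(sol_mols, inside_mols)
  if (length(rest) >= micelle_min) {
    cl <- find_clusters(config, cutoff = cutoff, molecules = rest)
    for (cc in cl$clusters) {
      if (length(cc) >= micelle_min) labels[as.character(cc)] <- "micelle"
    }
  }
  n <- length(sol_mols)
  structure(list(fraction_inside = sum(labels == "inside") / n,
                 fraction_micelles = sum(labels == "micelle") / n,
                 free_count = sum(labels == "free"),
                 labels = labels, n_solute = n),
            class = "dpd_localization")
}

#' @export
print.dpd_localization <- function(x, ...) {
  cat(sprintf(
    "Solute localization over %d molecules: %.1f%% inside, %.1f%% in micelles, %d free\n",
    x$n_solute, 100 * x$fraction_inside, 100 * x$fraction_micelles,
    x$free_count))
  invisible(x)
}

#' Water exclusion from a particle core
#'
#' Number density of W beads inside half the particle radius, divided by the
#' overall W density of the box.  Near zero for an assembled hydrophobic
#' core, near one for a uniform mixture.
#'
#' @param config A \code{dpd_config}.
#' @param particle Vector of molecule ids of the particle.
#' @return Dimensionless density ratio.
#' @export
water_exclusion <- function(config, particle) {
  if (!length(particle)) stop("empty particle")
  rad <- as.numeric(particle_diameter(config, particle)) / 2 /
    config$units$r_c
  prow <- cluster_bead_rows(config, particle)
  ctr <- pbc_center_of_mass(config$pos[prow, , drop = FALSE], config$box,
                            config$mass[prow])
  wrow <- which(config$species == "W")
  n_w <- length(wrow)
  if (!n_w) return(0)
  r <- sqrt(rowSums(min_image_disp(config$pos[wrow, , drop = FALSE], ctr,
                                   config$box)^2))
  core_r <- 0.5 * rad
  n_core <- sum(r < core_r)
  dens_core <- n_core / (4 / 3 * pi * core_r^3)
  dens_bulk <- n_w / prod(config$box)
  dens_core / dens_bulk
}
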