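# Independent oracles and fixture constructors used across the suite.

# Hand-built configuration from raw fields (reduced units).
make_config <- function(pos, species, box = c(10, 10, 10),
                        mol_id = seq_len(nrow(pos)),
                        mol_name = rep("custom", nrow(pos)),
                        bonds = matrix(integer(0), ncol = 2),
                        vel = NULL, mass = NULL, units = sim_units()) {
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  if (is.null(mass)) {
    reg <- default_bead_registry()
    mass <- ifelse(species %in% reg$name,
                   suppressWarnings(reg$mass[match(species, reg$name)]),
                   units$mass_da) / units$mass_da
  }
  dpdnano:::new_config(box, pos, vel, species, mol_id, mol_name, bonds,
                       units, seed = 0L, mass = mass)
}

min_image_r <- function(d, L) d - L * round(d / L)

# O(N^2) all-pairs conservative + bond forces in plain R: the reference the
# cell-list engine must match in the deterministic (gamma = sigma = 0) limit.
oracle_forces <- function(config, matrix, k_bond = 4, r0_bond = 0) {
  pos <- config$pos
  n <- nrow(pos)
  f <- base::matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- min_image_r(d, config$box)
      r <- sqrt(sum(d^2))
      if (r < 1 && r > 1e-12) {
        a <- matrix$a[config$species[i], config$species[j]]
        fv <- a * (1 - r) * d / r
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
      }
    }
  }
  if (nrow(config$bonds)) {
    for (b in seq_len(nrow(config$bonds))) {
      i <- config$bonds[b, 1]; j <- config$bonds[b, 2]
      d <- min_image_r(pos[i, ] - pos[j, ], config$box)
      r <- sqrt(sum(d^2))
      if (r > 1e-12) {
        fv <- -k_bond * (r - r0_bond) * d / r
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
      }
    }
  }
  f
}

# O(N^2) molecular clustering oracle: full distance matrix over filtered
# beads + graph components (igraph), independent of the cell-grid route.
oracle_clusters <- function(config, bead_filter, cutoff) {
  sel <- config$species %in% bead_filter
  pos <- config$pos[sel, , drop = FALSE]
  mid <- config$mol_id[sel]
  n <- nrow(pos)
  adj <- base::matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- min_image_r(pos[i, ] - pos[j, ], config$box)
      adj[i, j] <- sqrt(sum(d^2)) < cutoff
    }
  }
  mols <- sort(unique(mid))
  madj <- base::matrix(FALSE, length(mols), length(mols))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) {
        a <- match(mid[i], mols); b <- match(mid[j], mols)
        madj[a, b] <- TRUE
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(madj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(lapply(split(mols, comp), sort))
}

# canonical form for comparing cluster partitions
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, 0, 1))]
}

# uniform samplers for the closed-form shape oracles
sample_ball <- function(n, R, center = c(0, 0, 0)) {
  out <- base::matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    x <- base::matrix(stats::runif(3 * n, -R, R), ncol = 3)
    x <- x[rowSums(x^2) < R^2, , drop = FALSE]
    out <- rbind(out, x)
  }
  sweep(out[seq_len(n), , drop = FALSE], 2, center, `+`)
}

sample_slab <- function(n, a, b, t, center = c(0, 0, 0)) {
  # uniform in [-a/2,a/2] x [-b/2,b/2] x [-t,t] (half-thickness t)
  cbind(stats::runif(n, -a / 2, a / 2), stats::runif(n, -b / 2, b / 2),
        stats::runif(n, -t, t)) + rep(center, each = n)
}

# small random mixed configuration of single-bead molecules for property tests
random_point_config <- function(n, box, seed, species = "LA") {
  set.seed(seed)
  make_config(base::matrix(stats::runif(3 * n), ncol = 3) %*% diag(box),
              species = rep(species, n), box = box)
}

pam_matrix <- function() default_interaction_matrix("pam")
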