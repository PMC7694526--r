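test_that("pbc center of mass is immune to periodic wrap", {
  set.seed(1)
  box <- c(10, 10, 10)
  blob <- sweep(matrix(stats::rnorm(300, sd = 0.5), ncol = 3), 2, c(5, 5, 5), `+`)
  c1 <- pbc_center_of_mass(dpdnano:::wrap_positions(blob, box), box)
  expect_equal(c1, c(5, 5, 5), tolerance = 0.1)
  # shift the blob across the boundary: center must follow, modulo the box
  shifted <- dpdnano:::wrap_positions(sweep(blob, 2, c(4.8, 0, 0), `+`), box)
  c2 <- pbc_center_of_mass(shifted, box)
  circ <- (c2 - c1 - c(4.8, 0, 0)) %% box
  circ <- ifelse(circ > box / 2, circ - box, circ)  # signed circular residual
  expect_equal(circ, c(0, 0, 0), tolerance = 0.1)
})

test_that("clustering matches the O(N^2) union-find oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    set.seed(seed)
    n_mol <- 30
    centers <- matrix(stats::runif(3 * n_mol), ncol = 3) %*% diag(c(8, 8, 8))
    pos <- do.call(rbind, lapply(seq_len(n_mol), function(i) {
      sweep(matrix(stats::rnorm(9, sd = 0.2), ncol = 3), 2, centers[i, ], `+`)
    }))
    cfg <- make_config(pos, rep("LA", 3 * n_mol), box = c(8, 8, 8),
                       mol_id = rep(seq_len(n_mol), each = 3))
    got <- canon_clusters(find_clusters(cfg, "LA", cutoff = 1)$clusters)
    want <- canon_clusters(oracle_clusters(cfg, "LA", cutoff = 1))
    expect_identical(got, want, info = paste("seed", seed))
  }
})

test_that("clustering degenerate cases and filters", {
  # two molecules with closest filtered beads at 0.5 r_c -> one cluster
  cfg <- make_config(rbind(c(1, 1, 1), c(1.5, 1, 1)), c("F", "F"),
                     mol_id = c(1L, 2L))
  expect_length(find_clusters(cfg, "F")$clusters, 1)
  # all pairwise farther than the cutoff -> singletons
  cfg2 <- make_config(rbind(c(1, 1, 1), c(4, 4, 4), c(7, 7, 1)),
                      rep("F", 3), mol_id = 1:3)
  expect_length(find_clusters(cfg2, "F")$clusters, 3)
  expect_error(find_clusters(cfg2, character(0)), "empty bead filter")
  expect_error(find_clusters(cfg2, "F", cutoff = 0), "positive")
  # clusters partition the filtered molecule set
  cl <- find_clusters(cfg2, "F")
  expect_setequal(unlist(cl$clusters), 1:3)
})

test_that("cluster diameter recovers a uniform ball and basic invariances", {
  set.seed(10)
  R <- 2.5
  pos <- sample_ball(4000, R, center = c(10, 10, 10))
  cfg <- make_config(pos, rep("LA", 4000), box = c(20, 20, 20),
                     mol_id = rep(1L, 4000), mol_name = rep("PLA_70", 4000))
  d_nm <- cluster_diameter(cfg, 1L)
  expect_equal(d_nm, 2 * R * cfg$units$r_c / 10, tolerance = 0.03)
  # single bead -> 0
  one <- make_config(rbind(c(5, 5, 5)), "LA", mol_id = 1L)
  expect_equal(cluster_diameter(one, 1L), 0)
  # translation (with wrap) leaves the diameter unchanged
  cfg_t <- cfg
  cfg_t$pos <- dpdnano:::wrap_positions(sweep(cfg$pos, 2, c(9, 0, 3), `+`),
                                        cfg$box)
  expect_equal(cluster_diameter(cfg_t, 1L), d_nm, tolerance = 1e-9)
})

test_that("shape classification separates spheres from elongated objects", {
  set.seed(11)
  # points on a sphere surface: aspect ~ 1
  u <- matrix(stats::rnorm(3 * 2000), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 2 + 10
  sph <- make_config(u, rep("F", 2000), box = c(20, 20, 20),
                     mol_id = rep(1:10, each = 200))
  cls <- shape_class(sph, 1:10)
  expect_equal(as.character(cls), "sphere")
  expect_lt(attr(cls, "aspect"), 1.2)
  # cylinder with length 10x radius: wormlike
  cyl <- cbind(stats::runif(2000, -5, 5),
               stats::rnorm(2000, sd = 0.5), stats::rnorm(2000, sd = 0.5))
  # analytic aspect of a uniform cylinder L = 10 R: sqrt((L^2/12) / (R^2/4))
  cfgc <- make_config(sweep(cyl, 2, c(10, 10, 10), `+`), rep("F", 2000),
                      box = c(20, 20, 20), mol_id = rep(1:10, each = 200))
  clc <- shape_class(cfgc, 1:10)
  expect_equal(as.character(clc), "wormlike")
  # rigid rotation leaves the class unchanged
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cfgr <- cfgc
  cfgr$pos <- dpdnano:::wrap_positions(
    sweep(sweep(cfgc$pos, 2, c(10, 10, 10)) %*% t(rot), 2, c(10, 10, 10), `+`),
    cfgc$box)
  expect_equal(as.character(shape_class(cfgr, 1:10)), "wormlike")
  expect_error(shape_class(cfgc, 1:4), ">= 5 molecules")
})

test_that("bilayer thickness recovers a uniform slab and scales linearly", {
  set.seed(12)
  t_half <- 0.8
  pos <- sample_slab(6000, a = 8, b = 6, t = t_half, center = c(10, 10, 10))
  cfg <- make_config(pos, rep("F", 6000), box = c(20, 20, 20),
                     mol_id = rep(1:20, each = 300))
  th_nm <- bilayer_thickness(cfg, 1:20)
  expect_equal(th_nm, 2 * t_half * cfg$units$r_c / 10, tolerance = 0.03)
  # in-plane stretching leaves the thickness unchanged
  wide <- pos
  wide[, 1] <- (wide[, 1] - 10) * 1.5 + 10
  cfg_w <- make_config(wide, rep("F", 6000), box = c(20, 20, 20),
                       mol_id = rep(1:20, each = 300))
  expect_equal(bilayer_thickness(cfg_w, 1:20), th_nm, tolerance = 0.05)
  # doubling all coordinates doubles the thickness
  dbl <- sweep(sweep(pos, 2, c(10, 10, 10)) * 2, 2, c(10, 10, 10), `+`)
  cfg_d <- make_config(dbl, rep("F", 6000), box = c(40, 40, 40),
                       mol_id = rep(1:20, each = 300))
  expect_equal(bilayer_thickness(cfg_d, 1:20), 2 * th_nm, tolerance = 0.05)
  # sphere-class input is rejected
  ball <- make_config(sample_ball(3000, 2, c(10, 10, 10)), rep("F", 3000),
                      box = c(20, 20, 20), mol_id = rep(1:10, each = 300))
  expect_error(bilayer_thickness(ball, 1:10), "sphere-class")
})

test_that("particle diameter finds the half-max radius of a uniform ball", {
  set.seed(13)
  R <- 4
  n <- round(3 * 4 / 3 * pi * R^3)   # liquid density filling
  cfg <- make_config(sample_ball(n, R, c(10, 10, 10)), rep("LA", n),
                     box = c(20, 20, 20), mol_id = rep(1L, n),
                     mol_name = rep("PLA_70", n))
  d_A <- particle_diameter(cfg, 1L)
  expect_false(attr(d_A, "fallback"))
  expect_equal(as.numeric(d_A), 2 * R * cfg$units$r_c, tolerance = 0.05)
  # adding a distant molecule outside the cluster leaves the value unchanged
  cfg2 <- make_config(rbind(cfg$pos, c(1, 1, 1)), c(cfg$species, "LA"),
                      box = c(20, 20, 20), mol_id = c(cfg$mol_id, 2L),
                      mol_name = c(cfg$mol_name, "PLA_70"))
  expect_equal(as.numeric(particle_diameter(cfg2, 1L)), as.numeric(d_A))
  # degenerate input falls back to the gyration diameter with a flag
  tiny <- make_config(sample_ball(50, 1, c(5, 5, 5)), rep("LA", 50),
                      mol_id = rep(1L, 50), mol_name = rep("PLA_70", 50))
  expect_true(attr(particle_diameter(tiny, 1L), "fallback"))
})

test_that("radial ordering reports per-species mean distances", {
  set.seed(14)
  # K beads at 1.2 R, F beads at 0.6 R from the center
  R <- 3
  ctr <- c(10, 10, 10)
  onshell <- function(n, r) {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    sweep(u / sqrt(rowSums(u^2)) * r, 2, ctr, `+`)
  }
  pos <- rbind(onshell(200, 1.2 * R), onshell(200, 0.6 * R),
               sample_ball(500, R, ctr))
  cfg <- make_config(pos, c(rep("K", 200), rep("F", 200), rep("LA", 500)),
                     box = c(20, 20, 20),
                     mol_id = c(rep(1:40, each = 10), rep(41L, 500)),
                     mol_name = c(rep("Pam1CSK4", 400), rep("PLA_70", 500)))
  ro <- radial_ordering(cfg, 41L, "Pam1CSK4")
  expect_equal(unname(ro["K"] / ro["F"]), 2, tolerance = 0.05)
  # all beads at the center -> zero means
  allc <- make_config(matrix(10, 6, 3), c("K", "F", "K", "F", "LA", "LA"),
                      box = c(20, 20, 20), mol_id = c(1L, 1L, 2L, 2L, 3L, 3L),
                      mol_name = c(rep("Pam1CSK4", 4), rep("PLA_70", 2)))
  expect_equal(max(radial_ordering(allc, 3L, "Pam1CSK4")), 0)
  # global translation invariance
  cfg_t <- cfg
  cfg_t$pos <- dpdnano:::wrap_positions(sweep(cfg$pos, 2, c(7, 3, 9), `+`),
                                        cfg$box)
  ro_t <- radial_ordering(cfg_t, 41L, "Pam1CSK4")
  expect_equal(ro_t[["K"]], ro[["K"]], tolerance = 1e-9)
})

test_that("encapsulated fraction counts a constructed 75/25 split", {
  # host slab of LA; 9 solutes touching it, 3 in one distant micelle
  set.seed(15)
  box <- c(30, 10, 10)
  slab <- cbind(stats::runif(2000, 0, 5), stats::runif(2000, 0, 10),
                stats::runif(2000, 0, 10))
  chains <- rep(1:10, each = 200)
  place_solute <- function(x0, id) {
    cbind(stats::runif(4, x0, x0 + 0.4), stats::runif(4, 4, 4.4),
          stats::runif(4, 4, 4.4))
  }
  sol_pos <- do.call(rbind, c(
    lapply(1:9, function(k) place_solute(5.05, k)),       # touching the slab
    lapply(1:3, function(k) place_solute(20 + 0.2 * k, k))))  # micelle trio
  pos <- rbind(slab, sol_pos)
  species <- c(rep("LA", 2000), rep("F", nrow(sol_pos)))
  mol_id <- c(chains, rep(11:22, each = 4))
  mol_name <- c(rep("PLA_70", 2000), rep("Pam3CSK4", nrow(sol_pos)))
  cfg <- make_config(pos, species, box = box, mol_id = mol_id,
                     mol_name = mol_name)
  host <- largest_cluster(find_clusters(cfg, "LA"))
  rep_ <- encapsulated_fraction(cfg, host, "Pam3CSK4")
  expect_equal(rep_$fraction_inside, 0.75)
  expect_equal(rep_$fraction_micelles, 0.25)
  expect_equal(rep_$free_count, 0)
  # labels partition the solute set
  expect_length(rep_$labels, 12)
  expect_setequal(names(rep_$labels), as.character(11:22))
  # all solutes touching the slab -> fraction 1
  near <- cfg
  shift <- near$mol_id >= 20
  near$pos[shift, 1] <- near$pos[shift, 1] - 15.5
  rep2 <- encapsulated_fraction(near, host, "Pam3CSK4")
  expect_equal(rep2$fraction_inside, 1)
  expect_error(encapsulated_fraction(cfg, integer(0), "Pam3CSK4"), "host")
})

test_that("localization fractions sum to one on random configurations", {
  set.seed(16)
  for (k in 1:3) {
    box <- c(20, 10, 10)
    n_la <- 1500
    slab <- cbind(stats::runif(n_la, 0, 4), stats::runif(n_la, 0, 10),
                  stats::runif(n_la, 0, 10))
    n_sol <- 40
    sol <- matrix(stats::runif(3 * 4 * n_sol), ncol = 3) %*% diag(box)
    cfg <- make_config(rbind(slab, sol),
                       c(rep("LA", n_la), rep("F", 4 * n_sol)), box = box,
                       mol_id = c(rep(1:5, each = 300),
                                  rep(5 + seq_len(n_sol), each = 4)),
                       mol_name = c(rep("PLA_70", n_la),
                                    rep("Pam3CSK4", 4 * n_sol)))
    host <- largest_cluster(find_clusters(cfg, "LA"))
    rp <- encapsulated_fraction(cfg, host, "Pam3CSK4")
    expect_equal(rp$fraction_inside + rp$fraction_micelles +
                   rp$free_count / rp$n_solute, 1, tolerance = 1e-12)
  }
})

test_that("water exclusion is 0 for a dry core and ~1 for a uniform mix", {
  set.seed(17)
  R <- 4
  n_la <- round(3 * 4 / 3 * pi * R^3)
  core <- sample_ball(n_la, R, c(10, 10, 10))
  n_w <- round(3 * (20^3 - 4 / 3 * pi * R^3))
  shell_w <- matrix(NA_real_, 0, 3)
  while (nrow(shell_w) < n_w) {
    cand <- matrix(stats::runif(3 * n_w, 0, 20), ncol = 3)
    keep <- rowSums(sweep(cand, 2, c(10, 10, 10))^2) >= R^2
    shell_w <- rbind(shell_w, cand[keep, , drop = FALSE])
  }
  shell_w <- shell_w[seq_len(n_w), ]
  cfg <- make_config(rbind(core, shell_w),
                     c(rep("LA", n_la), rep("W", n_w)), box = c(20, 20, 20),
                     mol_id = c(rep(1L, n_la), 1L + seq_len(n_w)),
                     mol_name = c(rep("PLA_70", n_la), rep("water", n_w)))
  expect_equal(water_exclusion(cfg, 1L), 0)
  # uniform mixture: ratio about 1
  mix <- cfg
  mix$pos[cfg$species == "W", ] <- matrix(stats::runif(3 * n_w, 0, 20),
                                          ncol = 3)
  wx <- water_exclusion(mix, 1L)
  expect_gt(wx, 0.7)
  expect_lt(wx, 1.5)
})
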