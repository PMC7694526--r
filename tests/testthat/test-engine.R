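test_that("fluctuation-dissipation constraint is enforced at construction", {
  p <- dpd_params(gamma = 4.5, kT = 1)
  expect_equal(p$sigma, 3)
  expect_silent(dpd_params(gamma = 4.5, kT = 1, sigma = 3))
  expect_error(dpd_params(gamma = 4.5, kT = 1, sigma = 2.9),
               "fluctuation-dissipation")
})

test_that("conservative pair force is linear, cut off and antisymmetric", {
  m <- dpdnano:::new_interaction_matrix("X", matrix(25, 1, 1))
  two <- function(r) {
    make_config(rbind(c(2, 2, 2), c(2 + r, 2, 2)), c("X", "X"),
                box = c(10, 10, 10))
  }
  # r = 0.5 r_c, a = 25 -> magnitude 12.5 along the axis
  f <- dpd_forces(two(0.5), m)$forces
  expect_equal(f[1, ], c(-12.5, 0, 0))
  expect_equal(f[2, ], c(12.5, 0, 0))   # Newton's third law
  # r >= r_c -> zero
  expect_equal(dpd_forces(two(1), m)$forces, matrix(0, 2, 3))
  expect_equal(dpd_forces(two(1.7), m)$forces, matrix(0, 2, 3))
})

test_that("bond force is harmonic, restoring and linear in k", {
  m <- dpdnano:::new_interaction_matrix("X", matrix(1e-12, 1, 1))
  cfg <- make_config(rbind(c(2, 2, 2), c(2.5, 2, 2)), c("X", "X"),
                     bonds = cbind(1L, 2L), mol_id = c(1L, 1L))
  # k = 4, r0 = 0, r = 0.5 -> magnitude 2 pulling the pair together
  f4 <- dpd_forces(cfg, m, dpd_params(k_bond = 4, r0_bond = 0))$forces
  expect_equal(f4[1, 1], 2, tolerance = 1e-9)
  expect_equal(f4[2, 1], -2, tolerance = 1e-9)
  # at the rest length the force vanishes
  f0 <- dpd_forces(cfg, m, dpd_params(k_bond = 4, r0_bond = 0.5))$forces
  expect_equal(max(abs(f0)), 0, tolerance = 1e-9)
  # doubling k doubles the force
  f8 <- dpd_forces(cfg, m, dpd_params(k_bond = 8, r0_bond = 0))$forces
  expect_equal(f8, 2 * f4, tolerance = 1e-12)
})

test_that("cell-list forces match the all-pairs oracle to 1e-12", {
  m <- pam_matrix()
  set.seed(33)
  for (rep in 1:3) {
    n <- 50
    pos <- matrix(stats::runif(3 * n), ncol = 3) %*% diag(c(4, 4, 4))
    sp <- sample(m$species, n, replace = TRUE)
    bonds <- cbind(seq(1, 9, 2), seq(2, 10, 2))
    cfg <- make_config(pos, sp, box = c(4, 4, 4),
                       mol_id = c(rep(1:5, each = 2), 6:(n - 5)),
                       bonds = bonds)
    f_cell <- dpd_forces(cfg, m, method = "cell")$forces
    f_all <- dpd_forces(cfg, m, method = "allpairs")$forces
    f_ref <- oracle_forces(cfg, m)
    expect_lt(max(abs(f_cell - f_all)), 1e-12)
    expect_lt(max(abs(f_cell - f_ref)), 1e-10)
  }
})

test_that("thermostat forces vanish beyond the cutoff and keep pair sums zero", {
  m <- dpdnano:::new_interaction_matrix("X", matrix(1e-12, 1, 1))
  cfg <- make_config(rbind(c(2, 2, 2), c(2.5, 2, 2)), c("X", "X"))
  cfg$vel <- rbind(c(0.3, -0.2, 0.1), c(-0.1, 0.4, 0))
  f <- dpd_forces(cfg, m, thermostat = TRUE)$forces
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-14)
  far <- make_config(rbind(c(2, 2, 2), c(3.5, 2, 2)), c("X", "X"))
  far$vel <- cfg$vel
  expect_equal(dpd_forces(far, m, thermostat = TRUE)$forces,
               matrix(0, 2, 3), tolerance = 1e-14)
})

test_that("trivial runs behave: zero steps, zero forces, determinism", {
  m <- pam_matrix()
  cfg <- random_mixed_box(c(26, 26, 26), seed = 4)
  tr0 <- dpd_run(cfg, m, dpd_params(seed = 9), 0, 1)
  expect_length(tr0$snapshots, 1)
  expect_equal(final_snapshot(tr0)$pos, cfg$pos)
  # zero-velocity, zero-force configuration stays put
  lone <- make_config(rbind(c(5, 5, 5)), "W", box = c(10, 10, 10),
                      mol_name = "water")
  still <- dpd_run(lone, m, dpd_params(seed = 1), 10, 10, thermostat = FALSE)
  expect_equal(final_snapshot(still)$pos, lone$pos)
  # bit-exact reproducibility under one seed
  t1 <- dpd_run(cfg, m, dpd_params(seed = 5), 20, 20)
  t2 <- dpd_run(cfg, m, dpd_params(seed = 5), 20, 20)
  t3 <- dpd_run(cfg, m, dpd_params(seed = 6), 20, 20)
  expect_identical(final_snapshot(t1)$pos, final_snapshot(t2)$pos)
  expect_false(identical(final_snapshot(t1)$pos, final_snapshot(t3)$pos))
})

test_that("snapshot bookkeeping matches floor(n/stride) + 1 and the time map", {
  m <- pam_matrix()
  cfg <- random_mixed_box(c(20, 20, 20), seed = 2)
  tr <- dpd_run(cfg, m, dpd_params(seed = 3), 10, 3)
  expect_length(tr$snapshots, 10 %/% 3 + 1)
  expect_equal(tr$scalars$step, c(0, 3, 6, 9))
  expect_equal(tr$scalars$time_ps, c(0, 9, 18, 27))
})

test_that("momentum is conserved to accumulator precision over long runs", {
  m <- pam_matrix()
  cfg <- random_mixed_box(c(33, 33, 33), build_template("vitaminE"),
                          solute_pct = 0, seed = 8)
  tr <- dpd_run(cfg, default_interaction_matrix("vitE"),
                dpd_params(seed = 21), 10000, 2000)
  n <- n_beads(cfg)
  expect_true(all(tr$scalars$momentum_norm < 1e-6 * n))
})

test_that("pure water equilibrates to the target temperature within 3%", {
  m <- pam_matrix()
  cfg <- random_mixed_box(c(39, 39, 39), seed = 13)
  tr <- dpd_run(cfg, m, dpd_params(seed = 14), 2000, 100)
  kT <- tr$scalars$kT
  mean_kT <- mean(kT[tr$scalars$step >= 1000])
  expect_equal(mean_kT, 1, tolerance = 0.03)
})

test_that("gamma = sigma = 0 limit conserves energy like a symplectic scheme", {
  m <- dpdnano:::new_interaction_matrix("X", matrix(25, 1, 1))
  base <- make_config(rbind(c(5, 5, 5), c(5.6, 5, 5)), c("X", "X"),
                      bonds = cbind(1L, 2L), mol_id = c(1L, 1L))
  base$vel <- rbind(c(0.2, 0.1, 0), c(-0.2, -0.1, 0))
  drift <- function(dt) {
    tr <- dpd_run(base, m, dpd_params(dt = dt, gamma = 0, seed = 1),
                  1000, 10, thermostat = FALSE)
    e <- tr$scalars$pe + tr$scalars$ke
    list(drift = max(abs(e - e[1])), e0 = e[1])
  }
  d1 <- drift(0.04)$drift
  d2 <- drift(0.02)$drift
  expect_lt(d1 / drift(0.04)$e0, 0.02)
  # halving dt cuts the energy error by about 4 (O(dt^2) scheme)
  expect_gt(d1 / d2, 2.5)
})

test_that("water structure is liquid-like: first g(r) peak below r_c, no order", {
  m <- pam_matrix()
  cfg <- random_mixed_box(c(39, 39, 39), seed = 17)
  fin <- dpd_step(cfg, m, dpd_params(seed = 18), 500)
  pr <- dpdnano:::cpp_pairs_within(fin$pos, fin$box, 2.5)
  d <- fin$pos[pr$i, ] - fin$pos[pr$j, ]
  for (k in 1:3) d[, k] <- d[, k] - fin$box[k] * round(d[, k] / fin$box[k])
  r <- sqrt(rowSums(d^2))
  h <- graphics::hist(r, breaks = seq(0, 2.5, 0.05), plot = FALSE)
  n <- n_beads(fin)
  g <- h$counts / (0.5 * n * (n / prod(fin$box)) *
                     4 / 3 * pi * diff(h$breaks^3))
  expect_lt(h$mids[which.max(g)], 1)           # first peak inside the cutoff
  tail_g <- g[h$mids > 2]
  expect_lt(max(abs(tail_g - 1)), 0.15)        # no long-range order
})

test_that("species not covered by the matrix are rejected", {
  m <- default_interaction_matrix("vitE")
  cfg <- random_mixed_box(c(26, 26, 26), build_template("Pam1CSK4"), 10,
                          seed = 1)
  expect_error(dpd_run(cfg, m, dpd_params(), 1, 1), "species not covered")
})
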