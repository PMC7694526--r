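#' DPD integration parameters
#'
#' The thermostat follows the fluctuation-dissipation constraint
#' sigma^2 = 2 gamma kT exactly: \code{sigma} is derived from \code{gamma}
#' and \code{kT} and an explicitly supplied value is rejected unless it
#' satisfies the constraint.  Defaults are the standard choices for the
#' rho = 3 DPD liquid: gamma = 4.5 (so sigma = 3), dt = 0.04 reduced time,
#' velocity-predictor factor lambda = 0.65 (the value recommended for
#' gamma = 4.5, which holds the kinetic temperature within about 2 percent
#' at this time step; lambda = 0.5 reduces to plain velocity-Verlet),
#' harmonic bonds with k = 4 and zero rest length.
#'
#' @param dt Time step (reduced).
#' @param gamma Dissipative strength.
#' @param kT Target temperature (reduced).
#' @param sigma Optional noise amplitude; must equal sqrt(2 gamma kT).
#' @param lambda Velocity predictor factor of the modified velocity-Verlet.
#' @param k_bond,r0_bond Harmonic bond constant and rest length (reduced).
#' @param seed Integer seed for the pairwise random forces.
#' @return An object of class \code{dpd_params}.
#' @examples
#' dpd_params()$sigma  # 3
#' @export
dpd_params <- function(dt = 0.04, gamma = 4.5, kT = 1, sigma = NULL,
                       lambda = 0.65, k_bond = 4, r0_bond = 0, seed = 1) {
  stopifnot(dt > 0, gamma >= 0, kT > 0)
  s <- sqrt(2 * gamma * kT)
  if (!is.null(sigma) && abs(sigma^2 - 2 * gamma * kT) > 1e-12) {
    stop("fluctuation-dissipation violated: sigma^2 must equal 2 gamma kT")
  }
  structure(list(dt = dt, gamma = gamma, sigma = s, kT = kT, lambda = lambda,
                 k_bond = k_bond, r0_bond = r0_bond, seed = as.integer(seed)),
            class = "dpd_params")
}

species_index <- function(config, matrix) {
  idx <- match(config$species, matrix$species)
  if (anyNA(idx)) {
    stop("species not covered: ",
         paste(unique(config$species[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Run a DPD simulation
#'
#' Integrates the configuration for \code{n_steps} steps of the modified
#' velocity-Verlet scheme, recording a snapshot every \code{stride} steps
#' (plus the initial state).  Per-snapshot scalars (kinetic temperature,
#' momentum norm, potential and kinetic energy, elapsed physical time via
#' the ps-per-step mapping) are collected in a data frame.
#'
#' @param config A \code{dpd_config}.
#' @param matrix A \code{dpd_matrix} covering every species present.
#' @param params A \code{dpd_params}.
#' @param n_steps Number of integration steps (>= 0).
#' @param stride Snapshot interval in steps.
#' @param thermostat Logical; disable to run the symplectic gamma = sigma = 0
#'   limit (energy-conservation checks).
#' @return A \code{dpd_trajectory}: list with \code{snapshots} (list of
#'   \code{dpd_config}) and \code{scalars} (data frame).
#' @examples
#' cfg <- random_mixed_box(c(26, 26, 26), seed = 1)
#' tr <- dpd_run(cfg, default_interaction_matrix("pam"), dpd_params(), 10, 5)
#' tr$scalars
#' @export
dpd_run <- function(config, matrix, params = dpd_params(), n_steps,
                    stride = max(1L, n_steps %/% 20L), thermostat = TRUE) {
  stopifnot(n_steps >= 0, stride >= 1)
  idx <- species_index(config, matrix)
  res <- cpp_dpd_run(config$pos, config$vel, idx, config$mass, config$box,
                     matrix$a, config$bonds[, 1], config$bonds[, 2],
                     params$k_bond, params$r0_bond, params$gamma,
                     if (thermostat) params$sigma else 0,
                     params$dt, params$lambda,
                     as.integer(n_steps), as.integer(stride),
                     params$seed, thermostat)
  snaps <- lapply(seq_along(res$pos), function(i) {
    cfg <- config
    cfg$pos <- res$pos[[i]]
    cfg$vel <- res$vel[[i]]
    cfg
  })
  scal <- data.frame(step = res$step,
                     time_ps = res$step * config$units$ps_per_step,
                     kT = res$kT, momentum_norm = res$pnorm,
                     pe = res$pe, ke = res$ke)
  structure(list(snapshots = snaps, scalars = scal, params = params,
                 stride = as.integer(stride), units = config$units),
            class = "dpd_trajectory")
}

#' Advance a configuration by a number of steps
#'
#' Convenience wrapper around \code{\link{dpd_run}} returning only the final
#' configuration.
#'
#' @inheritParams dpd_run
#' @export
dpd_step <- function(config, matrix, params = dpd_params(), n_steps = 1,
                     thermostat = TRUE) {
  tr <- dpd_run(config, matrix, params, n_steps,
                stride = max(1L, as.integer(n_steps)), thermostat = thermostat)
  final_snapshot(tr)
}

#' Gentle warm-up of a freshly built configuration
#'
#' Freshly built configurations contain random-walk overlaps; a short run at
#' one tenth of the production time step relaxes them before production.
#'
#' @inheritParams dpd_run
#' @param steps Number of warm-up steps (default 100).
#' @return The relaxed \code{dpd_config}.
#' @export
dpd_warmup <- function(config, matrix, params = dpd_params(), steps = 100) {
  p <- params
  p$dt <- params$dt / 10
  dpd_step(config, matrix, p, steps)
}

#' Pairwise forces on every bead
#'
#' Evaluates the instantaneous forces (conservative + bond, plus the
#' dissipative and random terms when \code{thermostat = TRUE}) without
#' advancing the state.  \code{method = "allpairs"} bypasses the cell grid.
#'
#' @inheritParams dpd_run
#' @param method \code{"cell"} (cell-list search) or \code{"allpairs"}.
#' @return List with \code{forces} (N x 3) and \code{pe} (potential energy).
#' @export
dpd_forces <- function(config, matrix, params = dpd_params(),
                       thermostat = FALSE, method = c("cell", "allpairs")) {
  method <- match.arg(method)
  idx <- species_index(config, matrix)
  cpp_dpd_forces(config$pos, config$vel, idx, config$mass, config$box,
                 matrix$a, config$bonds[, 1], config$bonds[, 2],
                 params$k_bond, params$r0_bond, params$gamma,
                 if (thermostat) params$sigma else 0, params$dt,
                 params$seed, thermostat, method == "allpairs")
}

#' Final snapshot of a trajectory
#' @param trajectory A \code{dpd_trajectory}.
#' @export
final_snapshot <- function(trajectory) {
  trajectory$snapshots[[length(trajectory$snapshots)]]
}

#' Snapshots of the final fraction of a trajectory
#'
#' Headline observables are averaged over the last stretch of a run; the
#' default keeps the final 20 percent of snapshots.
#'
#' @param trajectory A \code{dpd_trajectory}.
#' @param fraction Fraction of snapshots (from the end) to keep.
#' @return List of \code{dpd_config}.
#' @export
tail_snapshots <- function(trajectory, fraction = 0.2) {
  n <- length(trajectory$snapshots)
  k <- max(1L, ceiling(fraction * n))
  trajectory$snapshots[(n - k + 1L):n]
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  n <- length(x$snapshots)
  last <- x$scalars[nrow(x$scalars), ]
  cat(sprintf(
    "DPD trajectory: %d snapshots (stride %d), %d steps = %.1f ns\n",
    n, x$stride, last$step, last$time_ps / 1000))
  cat(sprintf("  final kT = %.3f, |P| = %.2e\n", last$kT, last$momentum_norm))
  invisible(x)
}

#' Plot per-snapshot scalars of a trajectory
#'
#' @param x A \code{dpd_trajectory}.
#' @param which \code{"kT"}, \code{"energy"} or \code{"momentum"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.dpd_trajectory <- function(x, which = c("kT", "energy", "momentum"), ...) {
  which <- match.arg(which)
  s <- x$scalars
  switch(which,
    kT = {
      plot(s$time_ps / 1000, s$kT, type = "l", xlab = "time (ns)",
           ylab = "kinetic temperature (reduced)", ...)
      graphics::abline(h = x$params$kT, lty = 2)
    },
    energy = plot(s$time_ps / 1000, s$pe + s$ke, type = "l",
                  xlab = "time (ns)", ylab = "total energy (reduced)", ...),
    momentum = plot(s$time_ps / 1000, s$momentum_norm, type = "l",
                    xlab = "time (ns)", ylab = "|total momentum|", ...))
  invisible(x)
}
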