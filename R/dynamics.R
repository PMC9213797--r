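#' Integrator controls
#'
#' Parameters of the overdamped propagator. The default time step is
#' 0.05 ps for unconstrained chains and 0.2 ps with bond constraints (the
#' constraints remove the stiff bond forces that otherwise limit the
#' step). Hydrodynamic interactions, when enabled, are rebuilt every
#' `hi_update_interval` steps (default 400); non-bonded forces are
#' recomputed every `force_update_interval` steps (default 1; larger
#' values trade accuracy for speed on long chains), while bonded and
#' restraint forces are recomputed every step.
#'
#' @param max_steps Number of BD steps.
#' @param dt Time step, ps; default 0.2 with constraints, 0.05 without.
#'   Steps above 0.1 ps require `constraints_on = TRUE`.
#' @param snapshot_stride Record every this many steps (plus the initial
#'   state).
#' @param seed RNG seed recorded in provenance; `NULL` leaves the RNG
#'   state alone.
#' @param constraints_on Hold bond lengths fixed with SHAKE-style
#'   projection (bond tables are then dropped from the energy).
#' @param hi_on Use the Rotne-Prager-Yamakawa diffusion tensor instead of
#'   free-draining Stokes mobilities.
#' @param hi_update_interval Steps between diffusion-tensor rebuilds.
#' @param force_update_interval Steps between non-bonded force updates.
#' @param shake_tol Relative bond-length tolerance for the constraint
#'   projection.
#' @param shake_max_sweeps Sweep limit before a constraint failure is
#'   raised.
#' @param record_energy Also record the total energy at every snapshot.
#' @return A `bd_params` object.
#' @export
bd_params <- function(max_steps, dt = NULL, snapshot_stride = 1000,
                      seed = NULL, constraints_on = FALSE, hi_on = FALSE,
                      hi_update_interval = 400, force_update_interval = 1,
                      shake_tol = 1e-4, shake_max_sweeps = 500,
                      record_energy = FALSE) {
  if (is.null(dt)) dt <- if (constraints_on) 0.2 else 0.05
  stopifnot(dt > 0, max_steps >= 1, snapshot_stride >= 1,
            hi_update_interval >= 1, force_update_interval >= 1)
  if (dt > 0.1 && !constraints_on) {
    stop("time steps above 0.1 ps require bond constraints", call. = FALSE)
  }
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 snapshot_stride = as.integer(snapshot_stride),
                 seed = seed, constraints_on = constraints_on, hi_on = hi_on,
                 hi_update_interval = as.integer(hi_update_interval),
                 force_update_interval = as.integer(force_update_interval),
                 shake_tol = shake_tol,
                 shake_max_sweeps = as.integer(shake_max_sweeps),
                 record_energy = record_energy),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat("<bd_params> ", x$max_steps, " steps x ", x$dt, " ps",
      if (x$constraints_on) " (constrained)" else "",
      if (x$hi_on) paste0(", HI every ", x$hi_update_interval) else "",
      ", snapshots every ", x$snapshot_stride, "\n", sep = "")
  invisible(x)
}

#' Diffusion matrix of a system
#'
#' Free mode: block-diagonal Stokes-Einstein mobilities
#' D_i = kB T / (6 pi eta a_i). RPY mode: Rotne-Prager-Yamakawa pair
#' blocks with the standard overlapping-sphere correction, symmetric and
#' positive semidefinite for equal radii. Units A^2/ps.
#'
#' @param system A `bd_system`.
#' @param mode `"free"` or `"rpy"`.
#' @return A 3N x 3N numeric matrix (bead i occupies rows/cols 3i-2..3i).
#' @export
diffusion_matrix <- function(system, mode = c("free", "rpy")) {
  mode <- match.arg(mode)
  if (system$viscosity <= 0) {
    stop("viscosity must be positive", call. = FALSE)
  }
  pos <- system_positions(system)
  radius <- unlist(lapply(system$chains, function(c) c$beads$radius))
  if (mode == "rpy") {
    return(cpp_rpy_matrix(pos, radius, system$temperature,
                          system$viscosity))
  }
  kT <- .kB * system$temperature
  visc_conv <- 4184 / 6.02214076e23 / 1e-13 * 1e8
  d <- visc_conv * kT / (6 * pi * system$viscosity * radius)
  diag(rep(d, each = 3))
}

#' One Ermak-McCammon step
#'
#' delta r = (dt / kB T) D F + xi with xi zero-mean Gaussian of covariance
#' 2 D dt, correlated through a Cholesky factor of D. The mobility
#' divergence term is omitted (free and RPY tensors are divergence-free).
#' This is the reference step used for unit checks; [run_bd()] propagates
#' with the same rule in compiled code.
#'
#' @param positions N x 3 matrix, A.
#' @param forces N x 3 matrix, kcal/mol/A.
#' @param D Diffusion operator: 3N x 3N matrix, or a length-N (per-bead)
#'   or length-3N diagonal, A^2/ps.
#' @param dt Time step, ps.
#' @param temperature Kelvin.
#' @param noise Draw the random displacement (`FALSE` gives pure drift).
#' @return New N x 3 positions.
#' @export
bd_step <- function(positions, forces, D, dt, temperature = 298,
                    noise = TRUE) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            all(dim(forces) == dim(positions)), dt > 0)
  if (!all(is.finite(forces))) stop("forces must be finite", call. = FALSE)
  n3 <- 3L * nrow(positions)
  kT <- .kB * temperature
  f <- as.numeric(t(forces))
  if (is.matrix(D)) {
    stopifnot(nrow(D) == n3, ncol(D) == n3)
    L <- tryCatch(t(chol(D + 1e-12 * mean(diag(D)) * diag(n3))),
                  error = function(e) {
                    stop("diffusion matrix factorization failed: not ",
                         "positive semidefinite", call. = FALSE)
                  })
    dx <- (dt / kT) * as.numeric(D %*% f)
    if (noise) dx <- dx + sqrt(2 * dt) * as.numeric(L %*% stats::rnorm(n3))
  } else {
    dvec <- if (length(D) == nrow(positions)) rep(D, each = 3) else D
    stopifnot(length(dvec) == n3, all(dvec >= 0))
    dx <- (dt / kT) * dvec * f
    if (noise) dx <- dx + sqrt(2 * dvec * dt) * stats::rnorm(n3)
  }
  positions + matrix(dx, ncol = 3, byrow = TRUE)
}

#' Project bond constraints
#'
#' SHAKE-style iterative pairwise correction: each violated bond is fixed
#' by moving its two beads symmetrically along the current bond direction,
#' sweeping over all bonds until every length is within `tol` (relative)
#' of its target. The center of an isolated pair is preserved exactly.
#'
#' @param positions Trial N x 3 positions.
#' @param bonds M x 2 matrix of 1-based bead indices.
#' @param targets Length-M target distances, A.
#' @param tol Relative tolerance.
#' @param max_sweeps Iteration limit; non-convergence is an error naming
#'   the worst bond.
#' @return List with `positions`, `sweeps`, `worst_deviation`.
#' @export
constrain_bonds <- function(positions, bonds, targets, tol = 1e-4,
                            max_sweeps = 500) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            nrow(bonds) == length(targets), all(targets > 0))
  b <- matrix(as.integer(bonds - 1L), ncol = 2)
  res <- cpp_shake(positions, b, as.numeric(targets), tol,
                   as.integer(max_sweeps))
  if (!res$converged) {
    stop("bond constraints failed to converge after ", max_sweeps,
         " sweeps (worst bond ", res$worst_bond, ", relative deviation ",
         signif(res$worst_deviation, 3), ")", call. = FALSE)
  }
  res[c("positions", "sweeps", "worst_deviation")]
}

#' Half-harmonic restraint force
#'
#' Zero inside the cap; beyond it the energy is k (d - cap)^2 / 2 and each
#' bead feels a restoring force of magnitude k (d - cap) along the
#' separation axis (equal and opposite).
#'
#' @param positions N x 3 matrix.
#' @param bead_a,bead_b 1-based bead indices.
#' @param cap_distance Cap, A.
#' @param spring_constant k, kcal/mol/A^2.
#' @return List with `forces` (N x 3, zero except the two beads) and
#'   `energy`.
#' @export
restraint_force <- function(positions, bead_a, bead_b, cap_distance,
                            spring_constant) {
  f <- matrix(0, nrow(positions), 3)
  rij <- positions[bead_a, ] - positions[bead_b, ]
  d <- sqrt(sum(rij^2))
  e <- 0
  if (d > cap_distance && d > 0) {
    ext <- d - cap_distance
    e <- 0.5 * spring_constant * ext^2
    fa <- -spring_constant * ext * rij / d
    f[bead_a, ] <- fa
    f[bead_b, ] <- -fa
  }
  list(forces = f, energy = e)
}

#' Run a Brownian dynamics trajectory
#'
#' Propagates the system with the Ermak-McCammon rule: non-bonded forces
#' (scaled spline tables plus screened electrostatics) are recomputed
#' every `force_update_interval` steps, bonded and restraint forces every
#' step, and the diffusion tensor every `hi_update_interval` steps when
#' hydrodynamic interactions are on. With `constraints_on` every bond is
#' projected back to its target length after each step and bond tables are
#' dropped from the forces. Snapshots (including the initial state) are
#' recorded every `snapshot_stride` steps. A fixed `seed` reproduces the
#' trajectory bit for bit.
#'
#' @param system A `bd_system`.
#' @param ff A `bd_forcefield`.
#' @param params A `bd_params`.
#' @return A `bd_trajectory`: list with `times` (ps), `coords`
#'   (beads x 3 x snapshots), `energies` (if recorded), the originating
#'   `system` and `params`, and a `provenance` list (seed, package
#'   version).
#' @export
run_bd <- function(system, ff, params) {
  stopifnot(inherits(system, "bd_system"), inherits(ff, "bd_forcefield"),
            inherits(params, "bd_params"))
  cs <- .compile_system(system, ff, constraints_on = params$constraints_on,
                        require_bond_tables = TRUE)
  if (!is.null(params$seed)) set.seed(params$seed)
  res <- cpp_run_bd(cs, .tables_for_cpp(ff), unclass(params))
  structure(list(times = as.numeric(res$times), coords = res$coords,
                 energies = if (params$record_energy) {
                   as.numeric(res$energies)
                 },
                 system = system, params = params,
                 provenance = list(
                   seed = params$seed,
                   scaling_factor = ff$scaling_factor,
                   package_version =
                     as.character(utils::packageVersion("idpbd")))),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat("<bd_trajectory> ", dim(x$coords)[1], " beads, ",
      length(x$times), " snapshots over ",
      format(max(x$times), big.mark = ","), " ps (dt = ", x$params$dt,
      " ps)\n", sep = "")
  invisible(x)
}

# positions of snapshot s, optionally restricted to one chain
.snapshot_positions <- function(traj, s, chain = NULL) {
  pos <- traj$coords[, , s, drop = FALSE]
  dim(pos) <- dim(traj$coords)[1:2]
  if (!is.null(chain)) {
    sz <- .system_sizes(traj$system)
    pos <- pos[sz$offset[chain] + seq_len(sz$n[chain]), , drop = FALSE]
  }
  pos
}
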