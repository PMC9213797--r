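#' Bead-per-residue chain
#'
#' Internal constructor for the chain container: an ordered set of beads
#' (one per residue) with implicit consecutive bonds. Bond targets default
#' to the consecutive bead distances at construction, which is what the
#' constraint machinery holds fixed during dynamics.
#'
#' @param beads Tibble with columns `residue` (one-letter code), `charge`,
#'   `radius`, `x`, `y`, `z`.
#' @param name Label.
#' @return A `bd_chain` object.
#' @export
bd_chain <- function(beads, name = "chain") {
  stopifnot(is.data.frame(beads),
            all(c("residue", "charge", "radius", "x", "y", "z") %in%
                  names(beads)))
  beads <- tibble::as_tibble(beads)
  if (nrow(beads) < 1) stop("a chain needs at least one bead", call. = FALSE)
  if (any(beads$radius <= 0)) stop("bead radii must be positive", call. = FALSE)
  pos <- as.matrix(beads[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("bead positions must be finite", call. = FALSE)
  n <- nrow(beads)
  targets <- if (n > 1) {
    sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
  } else numeric(0)
  structure(list(beads = beads, bond_targets = targets, name = name),
            class = "bd_chain")
}

#' @export
print.bd_chain <- function(x, ...) {
  cat("<bd_chain> ", x$name, ": ", nrow(x$beads), " beads, ",
      length(x$bond_targets), " bonds\n", sep = "")
  print(x$beads, n = 5)
  invisible(x)
}

.chain_positions <- function(chain) {
  as.matrix(chain$beads[, c("x", "y", "z")])
}

.set_chain_positions <- function(chain, pos) {
  chain$beads$x <- pos[, 1]
  chain$beads$y <- pos[, 2]
  chain$beads$z <- pos[, 3]
  chain
}

#' Build a synthetic bead chain from a sequence
#'
#' Stand-in starting-structure generator: places one bead per residue at a
#' fixed consecutive (pseudo-Calpha) spacing in an extended line, an ideal
#' helix (1.5 A rise, 100 degree twist per residue, helix radius chosen so
#' consecutive beads sit exactly `bond_length` apart), or a random coil
#' (random-direction walk with fixed bond length; no self-avoidance).
#' Charges follow the neutral-pH convention of [net_charge_per_residue()].
#'
#' @param seq One-letter amino-acid string.
#' @param conformation `"extended"`, `"helix"` or `"random-coil"`.
#' @param bond_length Consecutive bead spacing, A (default 3.8).
#' @param radius Bead radius, A (default 4).
#' @param seed RNG seed for the random coil; same seed, same coordinates.
#' @param name Chain label; defaults to the sequence's name if present.
#' @return A `bd_chain`.
#' @examples
#' build_chain("EK", "extended")
#' @export
build_chain <- function(seq, conformation = c("extended", "helix",
                                              "random-coil"),
                        bond_length = 3.8, radius = 4.0, seed = NULL,
                        name = NULL) {
  conformation <- match.arg(conformation)
  res <- .split_seq(unname(seq))
  n <- length(res)
  if (is.null(name)) name <- if (!is.null(names(seq))) names(seq) else "chain"
  pos <- switch(conformation,
    extended = cbind(bond_length * (seq_len(n) - 1), 0, 0),
    helix = {
      rise <- 1.5
      twist <- 100 * pi / 180
      rad <- sqrt(bond_length^2 - rise^2) / (2 * sin(twist / 2))
      i <- seq_len(n) - 1
      cbind(rad * cos(i * twist), rad * sin(i * twist), rise * i)
    },
    `random-coil` = {
      if (!is.null(seed)) set.seed(seed)
      p <- matrix(0, n, 3)
      if (n > 1) {
        for (i in 2:n) {
          v <- stats::rnorm(3)
          p[i, ] <- p[i - 1, ] + bond_length * v / sqrt(sum(v^2))
        }
      }
      p
    })
  ch <- .aa_charge_vec()
  bd_chain(tibble::tibble(residue = res, charge = unname(ch[res]),
                          radius = radius, x = pos[, 1], y = pos[, 2],
                          z = pos[, 3]),
           name = name)
}

#' Simulation system
#'
#' One or two chains plus the solvent/electrostatic context: temperature,
#' dielectric constant, Debye screening length, solvent viscosity, and any
#' half-harmonic distance restraints between beads.
#'
#' @param chains A `bd_chain` or list of one or two `bd_chain`s.
#' @param temperature Kelvin (default 298).
#' @param dielectric Relative dielectric constant (default 78.4, water).
#' @param debye_length Screening length, A (default 7.85, the 150 mol/m3
#'   NaCl value at 298 K; see [debye_length()]).
#' @param viscosity Solvent viscosity, cP (default 0.89, water at 298 K).
#' @param restraints Tibble with columns `chain_a`, `bead_a`, `chain_b`,
#'   `bead_b`, `cap_distance`, `spring_constant` (half-harmonic beyond the
#'   cap). Default none.
#' @param electrostatics Include screened Coulomb interactions (default
#'   TRUE; they also switch off when all charges are zero).
#' @return A `bd_system`.
#' @export
bd_system <- function(chains, temperature = 298, dielectric = 78.4,
                      debye_length = 7.85, viscosity = 0.89,
                      restraints = NULL, electrostatics = TRUE) {
  if (inherits(chains, "bd_chain")) chains <- list(chains)
  stopifnot(length(chains) %in% c(1L, 2L),
            all(vapply(chains, inherits, logical(1), "bd_chain")),
            temperature > 0, dielectric > 0, debye_length > 0, viscosity > 0)
  if (is.null(restraints)) {
    restraints <- tibble::tibble(chain_a = integer(), bead_a = integer(),
                                 chain_b = integer(), bead_b = integer(),
                                 cap_distance = numeric(),
                                 spring_constant = numeric())
  }
  stopifnot(all(restraints$cap_distance > 0),
            all(restraints$spring_constant >= 0))
  structure(list(chains = chains, temperature = temperature,
                 dielectric = dielectric, debye_length = debye_length,
                 viscosity = viscosity, restraints = restraints,
                 electrostatics = electrostatics),
            class = "bd_system")
}

#' @export
print.bd_system <- function(x, ...) {
  cat("<bd_system> ", length(x$chains), " chain(s), ",
      sum(vapply(x$chains, function(c) nrow(c$beads), integer(1))),
      " beads | T = ", x$temperature, " K, eps = ", x$dielectric,
      ", lambda_D = ", x$debye_length, " A, eta = ", x$viscosity, " cP\n",
      sep = "")
  if (nrow(x$restraints) > 0) {
    cat("restraints:\n")
    print(x$restraints)
  }
  invisible(x)
}

# total bead count and flat index offsets per chain
.system_sizes <- function(system) {
  ns <- vapply(system$chains, function(c) nrow(c$beads), integer(1))
  list(n = ns, offset = cumsum(c(0L, ns))[seq_along(ns)])
}

#' System coordinates as a matrix
#'
#' @param system A `bd_system`.
#' @return Numeric matrix (total beads x 3), chains stacked in order.
#' @export
system_positions <- function(system) {
  do.call(rbind, lapply(system$chains, .chain_positions))
}

# rotation matrix taking unit vector u onto unit vector v (Rodrigues)
.rotation_onto <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- p - sum(p * u) * u
    a <- a / sqrt(sum(a^2))
    return(2 * outer(a, a) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + wx + wx %*% wx / (1 + c_)
}

# principal axis of a coordinate set, sign fixed along the end-to-end vector
.principal_axis <- function(pos) {
  cen <- colMeans(pos)
  x <- sweep(pos, 2, cen)
  ax <- svd(x, nu = 0, nv = 1)$v[, 1]
  e2e <- pos[nrow(pos), ] - pos[1, ]
  if (sum(ax * e2e) < 0) ax <- -ax
  ax
}

# index (1-based) of the middle bead: floor(N/2) 0-based, for any parity
.middle_index <- function(n) n %/% 2L + 1L

#' Two-chain crosswise starting geometry
#'
#' Places two chains in the pairwise starting arrangement used for
#' association runs: each chain is translated so its middle Calpha sits at
#' the origin and rotated so its principal axis lies along x (chain A) or
#' y (chain B) — i.e. the chains are oriented crosswise — then chain B is
#' translated `separation` along +z. A half-harmonic restraint between the
#' two middle beads with the given cap keeps the pair associated.
#'
#' @param a,b `bd_chain` objects.
#' @param separation Middle-bead translation along z, A (default 15).
#' @param cap Restraint cap distance, A (default 20).
#' @param spring_constant Restraint stiffness beyond the cap,
#'   kcal/mol/A^2 (default 10).
#' @param ... Passed to [bd_system()] (temperature, debye_length, ...).
#' @return A `bd_system` with two chains and one restraint.
#' @examples
#' a <- build_chain(ek_variant("diblock"), "extended")
#' b <- build_chain(ek_variant("alternating"), "extended")
#' two_chain_system(a, b)
#' @export
two_chain_system <- function(a, b, separation = 15, cap = 20,
                             spring_constant = 10, ...) {
  place <- function(chain, target_axis, z_shift) {
    pos <- .chain_positions(chain)
    mid <- .middle_index(nrow(pos))
    pos <- sweep(pos, 2, pos[mid, ])
    if (nrow(pos) > 1) {
      rot <- .rotation_onto(.principal_axis(pos), target_axis)
      pos <- pos %*% t(rot)
      pos <- sweep(pos, 2, pos[mid, ])  # keep middle bead exactly at origin
    }
    pos[, 3] <- pos[, 3] + z_shift
    .set_chain_positions(chain, pos)
  }
  a2 <- place(a, c(1, 0, 0), 0)
  b2 <- place(b, c(0, 1, 0), separation)
  na <- nrow(a2$beads)
  nb <- nrow(b2$beads)
  restr <- tibble::tibble(chain_a = 1L, bead_a = .middle_index(na),
                          chain_b = 2L, bead_b = .middle_index(nb),
                          cap_distance = cap,
                          spring_constant = spring_constant)
  bd_system(list(a2, b2), restraints = restr, ...)
}
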