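.as_positions <- function(x) {
  if (inherits(x, "bd_chain")) return(.chain_positions(x))
  if (inherits(x, "bd_system")) return(system_positions(x))
  stopifnot(is.matrix(x), ncol(x) == 3)
  x
}

#' Radius of gyration
#'
#' Root-mean-square bead distance from the unweighted centroid; the usual
#' compactness indicator for a chain snapshot.
#'
#' @param x N x 3 coordinate matrix, `bd_chain` or `bd_system`.
#' @return Rg in A.
#' @export
radius_of_gyration <- function(x) {
  pos <- .as_positions(x)
  cen <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, cen)^2)))
}

#' Kirkwood hydrodynamic radius
#'
#' Reciprocal of the mean inverse pairwise Calpha distance over all
#' distinct bead pairs: 1/Rh = < 1/r_ij >. Typically followed by
#' [calibrate_rh()] to match bead-shell hydrodynamics conventions.
#'
#' @inheritParams radius_of_gyration
#' @return Rh in A.
#' @export
kirkwood_rh <- function(x) {
  pos <- .as_positions(x)
  n <- nrow(pos)
  if (n < 2) stop("need at least 2 beads", call. = FALSE)
  d <- stats::dist(pos)
  if (any(d == 0)) {
    stop("singular configuration: coincident beads", call. = FALSE)
  }
  1 / mean(1 / d)
}

#' Linear Rh calibration
#'
#' Maps a Kirkwood Rh onto the bead-shell (HYDROPRO-convention) scale:
#' 1.186 * Rh + 1.03 (A).
#'
#' @param rh Kirkwood Rh value(s), A.
#' @return Calibrated Rh, A.
#' @export
calibrate_rh <- function(rh) {
  stopifnot(all(rh >= 0))
  1.186 * rh + 1.03
}

#' Per-snapshot scalar observable series
#'
#' Evaluates Rg or Rh for one chain (or the whole system) at every
#' snapshot of a trajectory.
#'
#' @param traj A `bd_trajectory`.
#' @param chain Chain index, or `NULL` for all beads.
#' @param calibrate Apply [calibrate_rh()] (Rh only).
#' @return Tibble with columns `time` (ps) and `value` (A).
#' @name observable_series
NULL

#' @rdname observable_series
#' @export
rg_series <- function(traj, chain = NULL) {
  tibble::tibble(
    time = traj$times,
    value = vapply(seq_along(traj$times), function(s) {
      radius_of_gyration(.snapshot_positions(traj, s, chain))
    }, numeric(1)))
}

#' @rdname observable_series
#' @export
rh_series <- function(traj, chain = NULL, calibrate = FALSE) {
  v <- vapply(seq_along(traj$times), function(s) {
    kirkwood_rh(.snapshot_positions(traj, s, chain))
  }, numeric(1))
  tibble::tibble(time = traj$times,
                 value = if (calibrate) calibrate_rh(v) else v)
}

#' Inter-residue distance profile
#'
#' Mean Calpha-Calpha distance as a function of sequence separation
#' |j - i|, averaged over all snapshots and all pairs at each separation
#' (N - k pairs per snapshot for separation k).
#'
#' @param traj A `bd_trajectory`.
#' @param chain Chain index (default 1).
#' @return Tibble with columns `separation`, `mean_distance` (A) and
#'   `n_pairs` (pairs per snapshot).
#' @export
rij_profile <- function(traj, chain = 1) {
  sz <- .system_sizes(traj$system)
  n <- sz$n[chain]
  if (n < 2) stop("need at least 2 beads", call. = FALSE)
  acc <- numeric(n - 1)
  for (s in seq_along(traj$times)) {
    pos <- .snapshot_positions(traj, s, chain)
    d <- as.matrix(stats::dist(pos))
    for (k in seq_len(n - 1)) {
      acc[k] <- acc[k] + mean(d[cbind(seq_len(n - k), seq_len(n - k) + k)])
    }
  }
  tibble::tibble(separation = seq_len(n - 1),
                 mean_distance = acc / length(traj$times),
                 n_pairs = n - seq_len(n - 1))
}

#' Entanglement index of a two-chain configuration
#'
#' Mean Calpha-Calpha distance over all inter-chain bead pairs (i in A,
#' j in B) — an association/interpenetration proxy: smaller values mean
#' the chains interpenetrate more.
#'
#' @param x A two-chain `bd_system`, or a list of two N x 3 matrices.
#' @return Index in A.
#' @export
entanglement_index <- function(x) {
  if (inherits(x, "bd_system")) {
    if (length(x$chains) != 2) {
      stop("entanglement index needs exactly two chains", call. = FALSE)
    }
    a <- .chain_positions(x$chains[[1]])
    b <- .chain_positions(x$chains[[2]])
  } else {
    stopifnot(is.list(x), length(x) == 2)
    a <- x[[1]]
    b <- x[[2]]
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  mean(sqrt(pmax(d2, 0)))
}

#' Entanglement index series over a trajectory
#'
#' @param traj A two-chain `bd_trajectory`.
#' @return Tibble with columns `time` and `value` (A).
#' @export
entanglement_series <- function(traj) {
  sz <- .system_sizes(traj$system)
  if (length(sz$n) != 2) {
    stop("entanglement index needs exactly two chains", call. = FALSE)
  }
  tibble::tibble(
    time = traj$times,
    value = vapply(seq_along(traj$times), function(s) {
      entanglement_index(list(.snapshot_positions(traj, s, 1),
                              .snapshot_positions(traj, s, 2)))
    }, numeric(1)))
}

#' Distance between two beads over a trajectory
#'
#' @param traj A `bd_trajectory`.
#' @param bead_a,bead_b Bead references `c(chain, residue)` (1-based), or a
#'   single flat bead index.
#' @return Tibble with columns `time` and `value` (A).
#' @export
distance_series <- function(traj, bead_a, bead_b) {
  flat <- function(ref) {
    sz <- .system_sizes(traj$system)
    if (length(ref) == 2) {
      if (ref[1] > length(sz$n) || ref[2] > sz$n[ref[1]] || any(ref < 1)) {
        stop("invalid bead reference (", ref[1], ", ", ref[2], ")",
             call. = FALSE)
      }
      sz$offset[ref[1]] + ref[2]
    } else {
      if (ref < 1 || ref > sum(sz$n)) {
        stop("invalid bead index ", ref, call. = FALSE)
      }
      ref
    }
  }
  ia <- flat(bead_a)
  ib <- flat(bead_b)
  tibble::tibble(
    time = traj$times,
    value = vapply(seq_along(traj$times), function(s) {
      pos <- .snapshot_positions(traj, s)
      sqrt(sum((pos[ia, ] - pos[ib, ])^2))
    }, numeric(1)))
}

#' Normalized autocorrelation of an observable series
#'
#' C(tau) = < (x_t - mu)(x_(t+tau) - mu) > / sigma^2 with mu and sigma^2
#' the full-series mean and (population) variance; C(0) = 1 by
#' construction. Used as the convergence check: a simulation is long
#' enough once the autocorrelations of its slow distances have decayed.
#'
#' @param x Numeric vector, or a series tibble with a `value` column.
#' @param max_lag Largest lag, in samples; must be < series length.
#' @return Tibble with columns `lag` (0..max_lag) and `acf`; all-`NA`
#'   `acf` (with a warning) for a constant series, where the
#'   normalization is undefined.
#' @export
autocorrelation <- function(x, max_lag) {
  if (is.data.frame(x)) x <- x$value
  n <- length(x)
  stopifnot(max_lag >= 1, n > max_lag)
  mu <- mean(x)
  sig2 <- mean((x - mu)^2)
  lags <- 0:max_lag
  if (sig2 == 0) {
    warning("constant series: autocorrelation undefined", call. = FALSE)
    return(tibble::tibble(lag = lags, acf = NA_real_))
  }
  xc <- x - mu
  vals <- vapply(lags, function(l) {
    mean(xc[seq_len(n - l)] * xc[seq_len(n - l) + l]) / sig2
  }, numeric(1))
  tibble::tibble(lag = lags, acf = vals)
}

#' Mean of an observable over a trajectory window
#'
#' Mean and naive standard error over the retained snapshots after
#' discarding a leading burn-in fraction. Snapshots are correlated, so the
#' per-run SE understates the true uncertainty; use [replica_summary()]
#' across independent runs for honest error bars.
#'
#' @param x Numeric vector, or a series tibble with a `value` column.
#' @param burn_in Fraction of leading snapshots to discard (default 0:
#'   whole-run averages).
#' @return Tibble with columns `mean`, `se`, `n_used`.
#' @export
trajectory_mean <- function(x, burn_in = 0) {
  if (is.data.frame(x)) x <- x$value
  stopifnot(burn_in >= 0, burn_in < 1)
  keep <- x[(floor(length(x) * burn_in) + 1):length(x)]
  if (length(keep) < 1) stop("empty retained window", call. = FALSE)
  tibble::tibble(mean = mean(keep),
                 se = if (length(keep) > 1) {
                   sd(keep) / sqrt(length(keep))
                 } else 0,
                 n_used = length(keep))
}

#' Across-replica mean with 95% confidence interval
#'
#' Arithmetic mean of independent-run means, standard error across runs,
#' and the 1.96 * SE half-width (95% CI convention).
#'
#' @param means Numeric vector of per-run means.
#' @return Tibble with columns `mean`, `se`, `ci95`, `n_replicas`.
#' @export
replica_summary <- function(means) {
  stopifnot(length(means) >= 1)
  se <- if (length(means) > 1) sd(means) / sqrt(length(means)) else 0
  tibble::tibble(mean = mean(means), se = se, ci95 = 1.96 * se,
                 n_replicas = length(means))
}
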