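#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into per-snapshot observables
#'
#' One row per snapshot and chain: time, radius of gyration, calibrated
#' Kirkwood Rh.
#'
#' @param x A `bd_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `chain`, `rg`, `rh_calibrated`.
#' @export
tidy.bd_trajectory <- function(x, ...) {
  purrr::map_dfr(seq_along(x$system$chains), function(ci) {
    rg <- rg_series(x, chain = ci)
    rh <- rh_series(x, chain = ci, calibrate = TRUE)
    tibble::tibble(time = rg$time, chain = ci, rg = rg$value,
                   rh_calibrated = rh$value)
  })
}

#' One-row trajectory summary
#'
#' @param x A `bd_trajectory`.
#' @param ... Unused.
#' @return Tibble with bead/snapshot counts, total time, and whole-run
#'   mean Rg and calibrated Rh (first chain).
#' @export
glance.bd_trajectory <- function(x, ...) {
  rg <- trajectory_mean(rg_series(x, chain = 1))
  rh <- trajectory_mean(rh_series(x, chain = 1, calibrate = TRUE))
  tibble::tibble(n_beads = dim(x$coords)[1],
                 n_snapshots = length(x$times),
                 total_time_ps = max(x$times),
                 mean_rg = rg$mean, mean_rh_calibrated = rh$mean)
}

#' @export
tidy.bd_scan <- function(x, ...) x$results

#' @export
glance.bd_scan <- function(x, ...) {
  tibble::tibble(reference_rh = x$reference_rh,
                 ideal_factor = x$ideal_factor,
                 n_factors = nrow(x$results),
                 n_replicas = x$n_replicas)
}

#' Plot per-chain Rg against time
#'
#' @param object A `bd_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bd_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$rg,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "Rg (Å)", colour = "chain")
}

#' Plot a scaling-factor scan
#'
#' Mean calibrated Rh (with 95% CI error bars) against the scaling
#' factor, with the reference Rh as a horizontal line and the
#' interpolated ideal factor marked when in range.
#'
#' @param object A `bd_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bd_scan <- function(object, ...) {
  df <- object$results
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$mean_rh)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_rh - .data$ci95,
                                          ymax = .data$mean_rh +
                                            .data$ci95)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$reference_rh,
                        linetype = "dashed") +
    ggplot2::labs(x = "non-bonded scaling factor s",
                  y = "calibrated Rh (Å)")
  if (!is.na(object$ideal_factor)) {
    p <- p + ggplot2::geom_vline(xintercept = object$ideal_factor,
                                 linetype = "dotted")
  }
  p
}

#' Plot an inter-residue distance profile
#'
#' @param profile Tibble from [rij_profile()] (optionally several,
#'   row-bound with a `label` column).
#' @return A ggplot of mean distance against sequence separation.
#' @export
plot_rij_profile <- function(profile) {
  aes <- if ("label" %in% names(profile)) {
    ggplot2::aes(.data$separation, .data$mean_distance,
                 colour = .data$label)
  } else {
    ggplot2::aes(.data$separation, .data$mean_distance)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "|j - i|", y = "mean Rij (Å)")
}
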