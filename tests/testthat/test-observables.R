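test_that("radius of gyration matches closed-form geometries", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(radius_of_gyration(two), 3)
  a <- 2.4
  square <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0))
  expect_equal(radius_of_gyration(square), a / sqrt(2))
})

test_that("Kirkwood Rh matches hand-enumerated configurations", {
  expect_equal(kirkwood_rh(rbind(c(0, 0, 0), c(10, 0, 0))), 10)
  tri <- rbind(c(0, 0, 0), c(6, 0, 0), c(3, 3 * sqrt(3), 0))
  expect_equal(kirkwood_rh(tri), 6)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  # pairs: 1, 1, 2 -> mean(1/r) = 5/6 -> Rh = 1.2
  expect_equal(kirkwood_rh(collinear), 1.2)
  expect_error(kirkwood_rh(rbind(c(0, 0, 0), c(0, 0, 0))), "[Ss]ingular")
  expect_error(kirkwood_rh(matrix(0, 1, 3)), "at least 2")
})

test_that("Rh calibration is the stated affine map", {
  expect_equal(calibrate_rh(0), 1.03)
  expect_equal(calibrate_rh(10), 12.89)
  expect_true(all(diff(calibrate_rh(c(1, 5, 20))) > 0))
})

test_that("size observables transform correctly under scaling and rigid motion", {
  set.seed(31)
  pos <- matrix(rnorm(30, sd = 5), 10, 3)
  rot <- .rotation_for_tests(c(1, 0.2, -0.5))
  moved <- sweep(pos %*% t(rot), 2, c(3, -7, 2), "+")
  expect_equal(radius_of_gyration(moved), radius_of_gyration(pos))
  expect_equal(kirkwood_rh(moved), kirkwood_rh(pos))
  alpha <- 2.7
  expect_equal(radius_of_gyration(alpha * pos),
               alpha * radius_of_gyration(pos))
  expect_equal(kirkwood_rh(alpha * pos), alpha * kirkwood_rh(pos))
  expect_lte(kirkwood_rh(pos), max(dist(pos)))
})

test_that("Rij profile of a rigid extended chain is linear in separation", {
  ch <- build_chain(paste(rep("G", 8), collapse = ""), "extended")
  sys <- bd_system(ch, electrostatics = FALSE)
  pos <- system_positions(sys)
  traj <- fake_trajectory(list(pos, pos, pos), sys)
  prof <- rij_profile(traj, chain = 1)
  expect_equal(prof$separation, 1:7)
  expect_equal(prof$mean_distance, 3.8 * (1:7))
  expect_equal(prof$n_pairs, 8 - (1:7))
})

test_that("entanglement index averages all inter-chain pairs", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 3, 0), c(1, 3, 0))
  expect_equal(entanglement_index(list(a, b)), (3 + sqrt(10)) / 2)
  expect_equal(entanglement_index(list(b, a)),
               entanglement_index(list(a, b)))
  # two single beads: plain distance
  expect_equal(entanglement_index(list(matrix(c(0, 0, 0), 1, 3),
                                       matrix(c(0, 0, 9), 1, 3))), 9)
  # common rigid motion leaves it unchanged; scaling scales it
  rot <- .rotation_for_tests(c(0.4, 1.1, -0.3))
  am <- sweep(a %*% t(rot), 2, c(1, 2, 3), "+")
  bm <- sweep(b %*% t(rot), 2, c(1, 2, 3), "+")
  expect_equal(entanglement_index(list(am, bm)),
               entanglement_index(list(a, b)))
  expect_equal(entanglement_index(list(2 * a, 2 * b)),
               2 * entanglement_index(list(a, b)))
  # one chain only is invalid
  sys1 <- bd_system(build_chain("EK", "extended"))
  expect_error(entanglement_index(sys1), "two chains")
})

test_that("distance series tracks the requested bead pair", {
  ch <- build_chain(paste(rep("G", 50), collapse = ""), "extended")
  sys <- bd_system(ch, electrostatics = FALSE)
  pos <- system_positions(sys)
  traj <- fake_trajectory(list(pos, pos), sys)
  ds <- distance_series(traj, c(1, 1), c(1, 50))
  expect_equal(nrow(ds), 2)
  expect_equal(ds$value, rep(49 * 3.8, 2))
  expect_error(distance_series(traj, c(1, 1), c(2, 3)), "invalid bead")
})

test_that("autocorrelation is exact for alternating and white series", {
  x <- rep(c(1, -1), 50)
  ac <- autocorrelation(x, max_lag = 3)
  expect_equal(ac$acf[ac$lag == 0], 1)
  expect_equal(ac$acf[ac$lag == 1], -1)
  expect_equal(ac$acf[ac$lag == 2], 1)

  set.seed(77)
  noise <- rnorm(1e4)
  acn <- autocorrelation(noise, max_lag = 10)
  expect_true(all(abs(acn$acf[-1]) < 3 / sqrt(1e4)))
  # cross-check against the standard estimator at small lag (divisor n vs
  # n - tau differ by O(tau/n))
  ref <- as.numeric(stats::acf(noise, lag.max = 5, plot = FALSE)$acf)
  expect_equal(acn$acf[1:6], ref, tolerance = 1e-2)

  expect_warning(res <- autocorrelation(rep(2, 10), 3), "constant")
  expect_true(all(is.na(res$acf)))
})

test_that("trajectory means, burn-in windows and replica CIs are exact", {
  expect_equal(trajectory_mean(rep(26, 10)),
               tibble::tibble(mean = 26, se = 0, n_used = 10L))
  tm <- trajectory_mean(1:10, burn_in = 0.5)
  expect_equal(tm$mean, 8)
  expect_equal(tm$n_used, 5L)
  rs <- replica_summary(c(26, 27))
  expect_equal(rs$mean, 26.5)
  expect_equal(rs$ci95, 1.96 * sd(c(26, 27)) / sqrt(2))
})

test_that("tidy and glance summarize trajectories", {
  sys <- two_chain_fixture(5, "diblock", separation = 6)
  ff <- wca_ff()
  traj <- run_bd(sys, ff, bd_params(max_steps = 200, snapshot_stride = 50,
                                    seed = 2, constraints_on = TRUE))
  td <- tidy(traj)
  expect_equal(nrow(td), 2 * length(traj$times))
  expect_true(all(c("time", "chain", "rg", "rh_calibrated") %in% names(td)))
  g <- glance(traj)
  expect_equal(g$n_beads, 10)
  expect_equal(g$n_snapshots, 5)
})
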