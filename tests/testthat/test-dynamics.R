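test_that("free diffusion matrix follows Stokes-Einstein", {
  ch <- build_chain("G", "extended", radius = 4)
  sys <- bd_system(ch)
  D <- diffusion_matrix(sys, "free")
  kT <- 0.0019872041 * 298
  conv <- 4184 / 6.02214076e23 / 1e-13 * 1e8
  d_expect <- conv * kT / (6 * pi * 0.89 * 4)
  expect_equal(diag(D), rep(d_expect, 3))
  expect_true(all(D[upper.tri(D)] == 0))
})

test_that("RPY blocks converge to free mobilities at large separation", {
  a <- build_chain("G", "extended")
  b <- build_chain("G", "extended")
  b$beads$x <- 1e6
  sys <- bd_system(list(a, b))
  D <- diffusion_matrix(sys, "rpy")
  Dfree <- diffusion_matrix(sys, "free")
  expect_equal(D, Dfree, tolerance = 1e-5)
})

test_that("RPY matrix is symmetric positive semidefinite with overlaps", {
  set.seed(13)
  ch <- build_chain(random_seq(10), "random-coil", seed = 13)
  sys <- bd_system(ch)
  D <- diffusion_matrix(sys, "rpy")
  expect_equal(D, t(D), tolerance = 1e-12)
  expect_gte(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("bd_step drift follows (dt/kBT) D F exactly", {
  pos <- matrix(c(0, 0, 0), 1, 3)
  f <- matrix(c(1, -2, 0.5), 1, 3)
  # no force, no noise: unchanged
  expect_equal(bd_step(pos, 0 * f, D = 0.06, dt = 0.1, noise = FALSE), pos)
  # diagonal mobility
  kT <- 0.0019872041 * 298
  out <- bd_step(pos, f, D = 0.06, dt = 0.1, noise = FALSE)
  expect_equal(out, pos + 0.1 * 0.06 / kT * f)
  # full-matrix mobility
  Dm <- diag(c(0.06, 0.05, 0.04))
  out2 <- bd_step(pos, f, D = Dm, dt = 0.1, noise = FALSE)
  expect_equal(out2, pos + 0.1 / kT * matrix(as.numeric(Dm %*% t(f)), 1, 3))
  # indefinite D is a structured error
  expect_error(bd_step(pos, f, D = diag(c(-1, 1, 1)), dt = 0.1),
               "positive semidefinite")
})

test_that("constraint projection restores bonds and preserves pair midpoints", {
  # already satisfied: unchanged
  pos <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  res <- constrain_bonds(pos, rbind(c(1, 2)), 3.8)
  expect_equal(res$positions, pos)

  # single bond stretched to twice its target
  stretched <- rbind(c(0, 0, 0), c(7.6, 0, 0))
  res2 <- constrain_bonds(stretched, rbind(c(1, 2)), 3.8)
  len <- sqrt(sum((res2$positions[2, ] - res2$positions[1, ])^2))
  expect_equal(len, 3.8, tolerance = 3.8 * 1e-4)
  expect_equal(colMeans(res2$positions), colMeans(stretched),
               tolerance = 1e-10)

  # a long noisy chain converges with every bond inside tolerance
  set.seed(5)
  chain_pos <- cbind(3.8 * (0:49), 0, 0) + matrix(rnorm(150, 0, 0.3), 50, 3)
  bonds <- cbind(1:49, 2:50)
  res3 <- constrain_bonds(chain_pos, bonds, rep(3.8, 49))
  lens <- sqrt(rowSums((res3$positions[2:50, ] -
                          res3$positions[1:49, ])^2))
  expect_true(all(abs(lens - 3.8) / 3.8 <= 1e-4))
  expect_lt(res3$sweeps, 500)
})

test_that("constraint failure reports the worst bond", {
  # contradictory constraints on a triangle cannot all be met
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.1, 0))
  bonds <- rbind(c(1, 2), c(2, 3), c(1, 3))
  expect_error(constrain_bonds(pos, bonds, c(1, 1, 5), max_sweeps = 50),
               "failed to converge")
})

test_that("half-harmonic restraint is flat inside the cap", {
  pos <- rbind(c(0, 0, 0), c(19, 0, 0))
  r <- restraint_force(pos, 1, 2, cap_distance = 20, spring_constant = 10)
  expect_equal(r$forces, matrix(0, 2, 3))
  expect_equal(r$energy, 0)

  pos2 <- rbind(c(0, 0, 0), c(22, 0, 0))
  r2 <- restraint_force(pos2, 1, 2, cap_distance = 20, spring_constant = 10)
  expect_equal(sqrt(sum(r2$forces[1, ]^2)), 20)
  expect_equal(r2$forces[1, ], -r2$forces[2, ])
  expect_equal(r2$forces[1, ], c(20, 0, 0))  # pulled back toward bead 2
  expect_equal(r2$energy, 0.5 * 10 * 4)
})

test_that("trajectories have the promised snapshot structure", {
  sys <- bd_system(build_chain("EKEK", "extended"), electrostatics = FALSE)
  ff <- harmonic_ff()
  p <- bd_params(max_steps = 1000, snapshot_stride = 100, seed = 3, dt = 0.05)
  traj <- run_bd(sys, ff, p)
  expect_length(traj$times, 11)
  expect_equal(traj$times, seq(0, 50, by = 5))
  expect_equal(dim(traj$coords), c(4, 3, 11))
  expect_equal(traj$coords[, , 1], system_positions(sys),
               ignore_attr = TRUE)
})

test_that("a fixed seed reproduces trajectories bit for bit", {
  sys <- two_chain_fixture(8, "diblock", separation = 6)
  ff <- wca_ff()
  p <- bd_params(max_steps = 500, snapshot_stride = 100, seed = 17,
                 constraints_on = TRUE)
  t1 <- run_bd(sys, ff, p)
  t2 <- run_bd(sys, ff, p)
  expect_identical(t1$coords, t2$coords)
  p2 <- p; p2$seed <- 18
  t3 <- run_bd(sys, ff, p2)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("hydrodynamic coupling changes dynamics but not energetics", {
  sys <- two_chain_fixture(5, "diblock", separation = 6)
  ff <- wca_ff()
  e <- total_energy(sys, ff)  # energies carry no HI dependence
  expect_equal(total_energy(sys, ff), e)
  p_hi <- bd_params(max_steps = 200, snapshot_stride = 50, seed = 4,
                    constraints_on = TRUE, hi_on = TRUE,
                    hi_update_interval = 50)
  traj <- run_bd(sys, ff, p_hi)  # runs and stays finite
  expect_true(all(is.finite(traj$coords)))
})

test_that("time steps above 0.1 ps require constraints", {
  expect_error(bd_params(max_steps = 10, dt = 0.2), "constraints")
  expect_silent(bd_params(max_steps = 10, dt = 0.2, constraints_on = TRUE))
})
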