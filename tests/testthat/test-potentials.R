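test_that("Debye length matches its closed form and scaling law", {
  # independent evaluation from the physical constants
  lam_oracle <- function(C, T_, eps) {
    sqrt(8.8541878128e-12 * eps * 1.380649e-23 * T_ /
           (2 * 1.602176634e-19^2 * 6.02214076e23 * C)) * 1e10
  }
  for (C in c(1, 150, 1250, 5000)) {
    expect_equal(debye_length(C), lam_oracle(C, 298, 78.4), tolerance = 1e-12)
    expect_equal(debye_length(4 * C), debye_length(C) / 2, tolerance = 1e-12)
  }
  expect_equal(debye_length(150, 400, 60), lam_oracle(150, 400, 60))
  expect_error(debye_length(0), "positive")
  expect_error(debye_length(150, temperature = -5), "positive")
})

test_that("table validation enforces the format contract", {
  expect_error(potential_table("bond", "b", c(1, 2, 3), c(0, 0, 0)),
               "4 knots")
  expect_error(potential_table("bond", "b", c(1, 2, 2, 3), rep(0, 4)),
               "strictly increasing")
  expect_error(potential_table("nonbonded", "nb", 1:5, c(1, 1, 1, 1, 0.5)),
               "end at 0")
  expect_silent(potential_table("nonbonded", "nb", 1:5, c(1, 1, 1, 1, 0)))
})

test_that("spline interpolation is exact at knots and matches splinefun", {
  knots <- seq(2, 6, length.out = 41)
  vals <- (knots - 3.8)^2
  tab <- potential_table("bond", "b", knots, vals)
  at_knots <- eval_potential(tab, knots)
  expect_equal(at_knots$energy, vals, tolerance = 1e-12)

  # independent oracle: natural spline from stats
  sf <- stats::splinefun(knots, vals, method = "natural")
  set.seed(1)
  x <- runif(200, 2, 6)
  expect_equal(eval_potential(tab, x)$energy, sf(x), tolerance = 1e-9)
})

test_that("spline derivative agrees with central finite differences", {
  knots <- seq(2, 6, length.out = 41)
  tab <- potential_table("bond", "b", knots, (knots - 3.8)^2)
  h <- 1e-6
  for (x in c(4.1, 2.7, 5.3)) {
    fd <- (eval_potential(tab, x + h)$energy -
             eval_potential(tab, x - h)$energy) / (2 * h)
    expect_equal(eval_potential(tab, x)$derivative, fd, tolerance = 1e-6)
  }
})

test_that("boundary rules: cutoff zero above, linear continuation below", {
  knots <- seq(2, 6, length.out = 21)
  nb <- potential_table("nonbonded", "nb", knots, c((21:2) * 0.1, 0))
  beyond <- eval_potential(nb, c(6, 6.5, 7))
  expect_equal(beyond$energy, c(0, 0, 0))
  expect_equal(beyond$derivative, c(0, 0, 0))
  below <- eval_potential(nb, c(1.0, 1.5, 1.9))
  expect_equal(diff(below$derivative), c(0, 0))  # constant slope
  expect_equal(diff(below$energy) / diff(below$x),
               below$derivative[1:2], tolerance = 1e-10)
})

test_that("angle tables normalize their argument into [0, 360)", {
  knots <- seq(0, 360, length.out = 37)
  tab <- potential_table("angle", "angle", knots, sin(knots * pi / 180))
  expect_equal(eval_potential(tab, 370)$energy,
               eval_potential(tab, 10)$energy)
  expect_equal(eval_potential(tab, -30)$energy,
               eval_potential(tab, 330)$energy)
})

test_that("screened Coulomb has the right limits and signs", {
  # huge screening length: unscreened Coulomb
  u <- screened_coulomb(1, 1, 5, lambda_d = 1e9)
  expect_equal(u$energy, 332.0637 / (78.4 * 5), tolerance = 1e-6)
  # r = lambda: e^-1 attenuation
  u1 <- screened_coulomb(1, 1, 7.85, lambda_d = 7.85)
  expect_equal(u1$energy, exp(-1) * 332.0637 / (78.4 * 7.85),
               tolerance = 1e-12)
  # opposite charges attract
  ua <- screened_coulomb(1, -1, 5, lambda_d = 7.85)
  expect_lt(ua$energy, 0)
  expect_lt(ua$force, 0)
  expect_error(screened_coulomb(1, 1, 0, 7.85), "[Ss]ingular")
})

test_that("synthetic tables track their analytic oracles", {
  ff <- synthetic_forcefield(
    bond = list(form = "harmonic", k = 1, r0 = 3.8, range = c(2, 6), n = 41),
    nonbonded = list(form = "gaussian_well", depth = 0.5, width = 0.8,
                     r0 = 5))
  expect_equal(eval_potential(ff$tables$bond, 3.8)$energy, 0,
               tolerance = 1e-12)
  oracle <- attr(ff, "oracle")
  set.seed(2)
  x <- runif(1000, 2, 6)
  err <- abs(eval_potential(ff$tables$bond, x)$energy - oracle$bond$u(x))
  expect_lt(max(err), 1e-3)
  nbt <- ff$tables[["nb:default"]]
  xn <- runif(1000, min(nbt$knots), max(nbt$knots))
  errn <- abs(eval_potential(nbt, xn)$energy - oracle[["nb:default"]]$u(xn))
  expect_lt(max(errn), 1e-3)
  expect_equal(nbt$values[length(nbt$values)], 0)
  # WCA table also terminates at zero at its cutoff
  wca <- wca_ff()$tables[["nb:default"]]
  expect_equal(wca$values[length(wca$values)], 0)
})

test_that("table text files round trip and reject bad input", {
  ff <- wca_ff()
  path <- withr::local_tempfile(fileext = ".tab")
  write_potential_tables(ff$tables, path)
  back <- read_potential_tables(path)
  expect_equal(names(back), names(ff$tables))
  for (key in names(back)) {
    expect_equal(back[[key]]$knots, ff$tables[[key]]$knots, tolerance = 1e-9)
    expect_equal(back[[key]]$values, ff$tables[[key]]$values,
                 tolerance = 1e-9)
    expect_equal(back[[key]]$kind, ff$tables[[key]]$kind)
  }
  bad <- c("bond b 4", "1 0", "2 0", "3 0", "2.5 0")  # non-monotone
  expect_error(read_potential_tables(bad), "strictly increasing")
})

test_that("total energy obeys the scaling and exclusion contracts", {
  sys <- two_chain_fixture(6, "diblock", separation = 6)
  ff0 <- wca_ff(s = 0)
  e0 <- total_energy(sys, ff0)
  expect_equal(e0$energy[e0$term == "nonbonded_table"], 0)

  ff1 <- wca_ff(s = 0.4)
  ff2 <- wca_ff(s = 0.8)
  e1 <- total_energy(sys, ff1)$energy[4]
  e2 <- total_energy(sys, ff2)$energy[4]
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("two isolated unit charges reproduce the closed-form energy", {
  a <- build_chain("K", "extended")
  b <- build_chain("K", "extended")
  b$beads$z <- 7.85
  sys <- bd_system(list(a, b), debye_length = 7.85)
  ff <- forcefield(list(), scaling_factor = 0)
  e <- total_energy(sys, ff)
  expect_equal(e$energy[e$term == "electrostatic"],
               332.0637 * exp(-1) / (78.4 * 7.85), tolerance = 1e-12)
})

test_that("1-2 and 1-3 pairs are excluded from non-bonded sums", {
  # 4-bead charged chain: only the (1,4) pair contributes
  ch <- build_chain("KKKK", "extended")
  sys <- bd_system(ch, debye_length = 7.85, viscosity = 0.89)
  ff <- forcefield(list(), scaling_factor = 0)
  e <- total_energy(sys, ff)$energy[5]
  r14 <- 3 * 3.8
  expect_equal(e, 332.0637 * exp(-r14 / 7.85) / (78.4 * r14),
               tolerance = 1e-12)
})

test_that("energies are invariant under rigid motions of the whole system", {
  sys <- random_two_chain(seed = 3)
  ff <- wca_ff()
  e_ref <- total_energy(sys, ff)$energy
  rot <- .rotation_for_tests(c(0.3, -1, 2))
  for (ci in 1:2) {
    pos <- as.matrix(sys$chains[[ci]]$beads[, c("x", "y", "z")])
    pos <- pos %*% t(rot)
    pos <- sweep(pos, 2, c(5, -3, 11), "+")
    sys$chains[[ci]]$beads$x <- pos[, 1]
    sys$chains[[ci]]$beads$y <- pos[, 2]
    sys$chains[[ci]]$beads$z <- pos[, 3]
  }
  expect_equal(total_energy(sys, ff)$energy, e_ref, tolerance = 1e-8)
})

test_that("missing non-bonded tables raise an error naming the pair", {
  ch <- build_chain("EK", "extended")
  sys <- bd_system(ch)
  ff <- forcefield(list(`nb:E:E` = potential_table(
    "nonbonded", "nb:E:E", 1:5, c(1, 0.5, 0.2, 0.1, 0))))
  expect_error(total_energy(sys, ff), "nb:E:K")
})

test_that("analytic forces match the numerical energy gradient", {
  # all term types at once: bond + angle + dihedral + WCA + electrostatics
  ff <- synthetic_forcefield(
    bond = list(form = "harmonic", k = 8, r0 = 3.8),
    angle = list(form = "harmonic_angle", k = 2, theta0 = 110),
    dihedral = list(form = "cosine_dihedral", k = 0.5, n_per = 3, phi0 = 0),
    nonbonded = list(form = "wca", epsilon = 0.3, sigma = 4),
    scaling_factor = 0.7)
  sys <- random_two_chain(seed = 8, n = 5)
  f_ana <- system_forces(sys, ff)
  pos0 <- system_positions(sys)
  h <- 1e-5
  energy_at <- function(pos) {
    s2 <- sys
    sz <- c(5, 5)
    off <- c(0, 5)
    for (ci in 1:2) {
      p <- pos[off[ci] + 1:5, , drop = FALSE]
      s2$chains[[ci]]$beads$x <- p[, 1]
      s2$chains[[ci]]$beads$y <- p[, 2]
      s2$chains[[ci]]$beads$z <- p[, 3]
    }
    sum(total_energy(s2, ff)$energy)
  }
  set.seed(9)
  for (trial in 1:6) {
    i <- sample(nrow(pos0), 1)
    c_ <- sample(3, 1)
    pp <- pos0; pp[i, c_] <- pp[i, c_] + h
    pm <- pos0; pm[i, c_] <- pm[i, c_] - h
    fd <- -(energy_at(pp) - energy_at(pm)) / (2 * h)
    expect_equal(f_ana[i, c_], fd, tolerance = 1e-4)
  }
})
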