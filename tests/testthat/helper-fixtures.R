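# shared test fixtures, all generated in code

# quick single-table force fields
harmonic_ff <- function(k = 10, r0 = 3.8, s = 1, n = 41, range = c(2, 6)) {
  synthetic_forcefield(bond = list(form = "harmonic", k = k, r0 = r0,
                                   range = range, n = n),
                       scaling_factor = s)
}

wca_ff <- function(epsilon = 0.3, sigma = 4, s = 0.786, bond_k = 20) {
  synthetic_forcefield(bond = list(form = "harmonic", k = bond_k, r0 = 3.8),
                       nonbonded = list(form = "wca", epsilon = epsilon,
                                        sigma = sigma),
                       scaling_factor = s)
}

# a small fully-featured random system for gradient checks
random_two_chain <- function(seed = 1, n = 5) {
  set.seed(seed)
  a <- build_chain(paste(sample(c("E", "K", "G", "A"), n, TRUE),
                         collapse = ""), "random-coil", seed = seed)
  b <- build_chain(paste(sample(c("E", "K", "G", "A"), n, TRUE),
                         collapse = ""), "random-coil", seed = seed + 1)
  two_chain_system(a, b, separation = 8, cap = 6, spring_constant = 3)
}

# hand-built static trajectory around known coordinates
fake_trajectory <- function(pos_list, system, dt = 0.1) {
  coords <- array(unlist(pos_list),
                  dim = c(nrow(pos_list[[1]]), 3, length(pos_list)))
  structure(list(times = (seq_along(pos_list) - 1) * dt, coords = coords,
                 system = system,
                 params = bd_params(max_steps = 1, dt = dt)),
            class = "bd_trajectory")
}

# proper rotation matrix about an arbitrary axis (Rodrigues, angle = |axis|)
.rotation_for_tests <- function(axis) {
  th <- sqrt(sum(axis^2))
  u <- axis / th
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * ux + (1 - cos(th)) * ux %*% ux
}

# random valid sequence with at least min_charged charged residues
random_seq <- function(n, min_charged = 0) {
  repeat {
    s <- paste(sample(aa_properties()$aa, n, TRUE), collapse = "")
    ch <- strsplit(s, "")[[1]] %in% c("D", "E", "K", "R")
    if (sum(ch) >= min_charged) return(s)
  }
}
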