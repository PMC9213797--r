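#' Debye screening length
#'
#' lambda_D = sqrt(eps0 * eps_r * kB * T / (2 e^2 N_A C)) in Angstrom, with
#' the ionic strength C in mol/m^3 (SI). C = 150 mol/m3 at 298 K in water
#' (eps_r 78.4) gives 7.85 A, C = 1250 gives 2.72 A; quadrupling C halves
#' the length.
#'
#' @param ionic_strength mol/m^3; must be positive.
#' @param temperature Kelvin.
#' @param dielectric Relative dielectric constant.
#' @return Screening length in A.
#' @examples
#' debye_length(150)   # 7.85
#' debye_length(1250)  # 2.72
#' @export
debye_length <- function(ionic_strength, temperature = 298,
                         dielectric = 78.4) {
  if (any(ionic_strength <= 0) || any(temperature <= 0)) {
    stop("ionic strength and temperature must be positive", call. = FALSE)
  }
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  e <- 1.602176634e-19       # C
  NA_ <- 6.02214076e23       # 1/mol
  lam_m <- sqrt(eps0 * dielectric * kB * temperature /
                  (2 * e^2 * NA_ * ionic_strength))
  lam_m * 1e10
}

.table_kinds <- c(bond = 0L, angle = 1L, dihedral = 2L, nonbonded = 3L)

#' Tabulated potential
#'
#' A named energy table: strictly increasing knots (A for distance terms,
#' degrees for angle/dihedral terms) and energies in kcal/mol, evaluated
#' as a natural cubic spline by [eval_potential()]. Non-bonded tables must
#' end at exactly zero at the last knot (the cutoff).
#'
#' @param kind `"bond"`, `"angle"`, `"dihedral"` or `"nonbonded"`.
#' @param key Term label: residue-pair like `"E:K"` for non-bonded tables
#'   (order-insensitive), free label otherwise.
#' @param knots Strictly increasing abscissae, at least 4.
#' @param values Energies at the knots, kcal/mol.
#' @return A `bd_potential_table`.
#' @export
potential_table <- function(kind, key, knots, values) {
  kind <- match.arg(kind, names(.table_kinds))
  if (length(knots) < 4) stop("need at least 4 knots", call. = FALSE)
  if (length(knots) != length(values)) {
    stop("knots and values differ in length", call. = FALSE)
  }
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (kind == "nonbonded" && abs(values[length(values)]) > 1e-12) {
    stop("non-bonded tables must end at 0 at the cutoff knot", call. = FALSE)
  }
  structure(list(kind = kind, key = key, knots = as.numeric(knots),
                 values = as.numeric(values)),
            class = "bd_potential_table")
}

#' Evaluate a tabulated potential
#'
#' Natural cubic spline through the knots; exact at each knot. Below the
#' first knot the first-boundary slope is continued linearly (a steep-core
#' wall with a continuous force); non-bonded tables return (0, 0) at and
#' beyond the last knot; angle/dihedral inputs are normalized into
#' \[0, 360) degrees.
#'
#' @param table A `bd_potential_table`.
#' @param x Evaluation points (A or degrees, per table kind).
#' @return Tibble with columns `x`, `energy` (kcal/mol) and `derivative`
#'   (kcal/mol per A or per degree).
#' @export
eval_potential <- function(table, x) {
  stopifnot(inherits(table, "bd_potential_table"))
  m <- cpp_spline_eval(table$knots, table$values, .table_kinds[[table$kind]],
                       as.numeric(x))
  tibble::tibble(x = as.numeric(x), energy = unname(m[, 1]),
                 derivative = unname(m[, 2]))
}

#' @export
print.bd_potential_table <- function(x, ...) {
  cat("<bd_potential_table> ", x$kind, " '", x$key, "': ",
      length(x$knots), " knots on [", min(x$knots), ", ", max(x$knots),
      "]\n", sep = "")
  invisible(x)
}

#' Debye-Hueckel screened Coulomb interaction
#'
#' U(r) = 332.0637 q1 q2 exp(-r/lambda_D) / (eps_r r) kcal/mol with r and
#' lambda_D in A and charges in elementary units; the returned force is
#' -dU/dr (positive = repulsive).
#'
#' @param q1,q2 Charges, e.
#' @param r Separation, A; must be positive.
#' @param lambda_d Screening length, A.
#' @param dielectric Relative dielectric constant.
#' @return Tibble with columns `r`, `energy`, `force`.
#' @export
screened_coulomb <- function(q1, q2, r, lambda_d, dielectric = 78.4) {
  if (any(r <= 0)) stop("singular distance: r must be positive", call. = FALSE)
  u <- .coulomb_const * q1 * q2 * exp(-r / lambda_d) / (dielectric * r)
  tibble::tibble(r = r, energy = u, force = u * (1 / lambda_d + 1 / r))
}

# canonical unordered pair key "nb:A:B" with sorted types
.nb_key <- function(a, b) {
  p <- sort(c(a, b))
  paste0("nb:", p[1], ":", p[2])
}

#' Force field container
#'
#' A set of tabulated potentials plus the global non-bonded scaling factor
#' s that multiplies every tabulated non-bonded energy (the screened
#' electrostatics are parameterized independently and are not scaled).
#' Table keys: `"bond"` (or `"bond:X:Y"` per sorted residue pair),
#' `"angle"`, `"dihedral"`, and `"nb:X:Y"` per sorted residue pair with an
#' optional `"nb:default"` fallback.
#'
#' @param tables Named list of `bd_potential_table`s.
#' @param scaling_factor Non-bonded scaling s in \[0, 1.5\]; default 0.786,
#'   the averaged ideal factor for disordered proteins.
#' @return A `bd_forcefield`.
#' @export
forcefield <- function(tables = list(), scaling_factor = 0.786) {
  stopifnot(is.list(tables),
            all(vapply(tables, inherits, logical(1), "bd_potential_table")),
            scaling_factor >= 0, scaling_factor <= 1.5)
  if (length(tables) > 0 && is.null(names(tables))) {
    names(tables) <- vapply(tables, `[[`, character(1), "key")
  }
  structure(list(tables = tables, scaling_factor = scaling_factor),
            class = "bd_forcefield")
}

#' @export
print.bd_forcefield <- function(x, ...) {
  cat("<bd_forcefield> s = ", x$scaling_factor, ", ",
      length(x$tables), " table(s): ",
      paste(names(x$tables), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# synthetic force field with analytic oracles

.ff_forms <- list(
  harmonic = function(p) {
    list(u = function(r) 0.5 * p$k * (r - p$r0)^2,
         du = function(r) p$k * (r - p$r0))
  },
  harmonic_angle = function(p) {
    # theta in degrees, k in kcal/mol/rad^2
    d2r <- pi / 180
    list(u = function(th) 0.5 * p$k * ((th - p$theta0) * d2r)^2,
         du = function(th) p$k * ((th - p$theta0) * d2r) * d2r)
  },
  cosine_dihedral = function(p) {
    d2r <- pi / 180
    list(u = function(ph) p$k * (1 + cos(p$n_per * ph * d2r - p$phi0 * d2r)),
         du = function(ph) -p$k * p$n_per * d2r * sin(p$n_per * ph * d2r -
                                                        p$phi0 * d2r))
  },
  wca = function(p) {
    # purely repulsive Weeks-Chandler-Andersen; zero at and beyond 2^(1/6) s
    rc <- 2^(1 / 6) * p$sigma
    list(u = function(r) {
      ifelse(r >= rc, 0,
             4 * p$epsilon * ((p$sigma / r)^12 - (p$sigma / r)^6) + p$epsilon)
    },
    du = function(r) {
      ifelse(r >= rc, 0,
             4 * p$epsilon * (-12 * p$sigma^12 / r^13 + 6 * p$sigma^6 / r^7))
    },
    cutoff = rc)
  },
  gaussian_well = function(p) {
    # attractive well of given depth/width, shifted to end at zero at cutoff
    rc <- p$r0 + 4 * p$width
    shift <- -p$depth * exp(-(rc - p$r0)^2 / (2 * p$width^2))
    list(u = function(r) {
      ifelse(r >= rc, 0,
             -p$depth * exp(-(r - p$r0)^2 / (2 * p$width^2)) - shift)
    },
    du = function(r) {
      ifelse(r >= rc, 0,
             p$depth * (r - p$r0) / p$width^2 *
               exp(-(r - p$r0)^2 / (2 * p$width^2)))
    },
    cutoff = rc)
  }
)

.sample_table <- function(kind, key, form, params, range, n) {
  f <- .ff_forms[[form]]
  if (is.null(f)) stop("unknown analytic form '", form, "'", call. = FALSE)
  f <- f(params)
  knots <- seq(range[1], range[2], length.out = n)
  vals <- f$u(knots)
  if (kind == "nonbonded") vals[n] <- 0  # exact zero at the cutoff knot
  list(table = potential_table(kind, key, knots, vals), oracle = f)
}

#' Synthetic force field with analytic oracles
#'
#' Builds spline tables sampled from closed-form potentials so the whole
#' pipeline can run and be tested without external tabulated data. Each
#' term spec is a list with a `form` and its parameters:
#' bond `list(form = "harmonic", k, r0, range, n)` (U = k/2 (r - r0)^2);
#' angle `list(form = "harmonic_angle", k, theta0, range, n)` (k per rad^2,
#' theta0 degrees); dihedral `list(form = "cosine_dihedral", k, n_per, phi0,
#' range, n)`; nonbonded `list(form = "wca", epsilon, sigma, n)` (repulsive
#' core, cutoff 2^(1/6) sigma) or `list(form = "gaussian_well", depth,
#' width, r0, n)` (well shifted to zero at r0 + 4 width). The exact
#' analytic energy/derivative functions are attached as the `"oracle"`
#' attribute, keyed like the tables.
#'
#' @param bond,angle,dihedral,nonbonded Term specs as above (`NULL` to
#'   omit). `nonbonded` may also be a named list of specs keyed `"nb:X:Y"`.
#' @param scaling_factor Non-bonded scaling s.
#' @return A `bd_forcefield` with an `"oracle"` attribute.
#' @examples
#' ff <- synthetic_forcefield(bond = list(form = "harmonic", k = 10, r0 = 3.8))
#' eval_potential(ff$tables[["bond"]], 3.8)$energy  # 0
#' @export
synthetic_forcefield <- function(bond = NULL, angle = NULL, dihedral = NULL,
                                 nonbonded = NULL, scaling_factor = 0.786) {
  tables <- list()
  oracle <- list()
  add <- function(kind, key, spec, default_range, default_n) {
    rng <- spec[["range"]] %||% default_range
    n <- spec[["n"]] %||% default_n
    params <- spec[setdiff(names(spec), c("form", "range", "n"))]
    st <- .sample_table(kind, key, spec[["form"]], params, rng, n)
    tables[[key]] <<- st$table
    oracle[[key]] <<- st$oracle
  }
  if (!is.null(bond)) {
    r0 <- bond[["r0"]] %||% 3.8
    add("bond", "bond", bond, c(max(0.5, r0 - 2), r0 + 2.2), 41L)
  }
  if (!is.null(angle)) add("angle", "angle", angle, c(0, 180), 61L)
  if (!is.null(dihedral)) add("dihedral", "dihedral", dihedral, c(0, 360), 73L)
  if (!is.null(nonbonded)) {
    specs <- if (!is.null(nonbonded[["form"]])) list(`nb:default` = nonbonded)
             else nonbonded
    for (key in names(specs)) {
      spec <- specs[[key]]
      rc <- .ff_forms[[spec[["form"]]]](
        spec[setdiff(names(spec), c("form", "range", "n"))])$cutoff
      lo <- if (spec[["form"]] == "wca") 0.8 * spec[["sigma"]]
            else max(0.5, spec[["r0"]] - 4 * spec[["width"]])
      add("nonbonded", key, spec, spec[["range"]] %||% c(lo, rc), 81L)
    }
  }
  ff <- forcefield(tables, scaling_factor)
  attr(ff, "oracle") <- oracle
  ff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# table text format

#' Write potential tables to a text file
#'
#' Dialect: `#` comment lines; per table a header `kind key n_knots`
#' followed by `n_knots` lines of `x value` (A or degrees; kcal/mol).
#'
#' @param tables `bd_potential_table`, or list of them.
#' @param path Output path; `NULL` returns the lines.
#' @return The lines, invisibly.
#' @export
write_potential_tables <- function(tables, path = NULL) {
  if (inherits(tables, "bd_potential_table")) tables <- list(tables)
  lines <- c("# idpbd tabulated potentials",
             "# kind key n_knots ; then n_knots lines of: x value")
  for (tab in tables) {
    lines <- c(lines,
               paste(tab$kind, tab$key, length(tab$knots)),
               sprintf("%.10g %.10g", tab$knots, tab$values))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read potential tables from a text file
#'
#' @param path Path or character lines in the [write_potential_tables()]
#'   dialect. Non-monotone knots are rejected.
#' @return Named list of `bd_potential_table`s.
#' @export
read_potential_tables <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) != 3L || !(hdr[1] %in% names(.table_kinds))) {
      stop("malformed table header at data line ", i, ": ", lines[i],
           call. = FALSE)
    }
    n <- as.integer(hdr[3])
    if (is.na(n) || i + n > length(lines)) {
      stop("truncated table '", hdr[2], "'", call. = FALSE)
    }
    block <- do.call(rbind,
                     strsplit(trimws(lines[(i + 1L):(i + n)]), "\\s+"))
    knots <- as.numeric(block[, 1])
    vals <- as.numeric(block[, 2])
    if (anyNA(knots) || anyNA(vals)) {
      stop("non-numeric knot data in table '", hdr[2], "'", call. = FALSE)
    }
    out[[hdr[2]]] <- potential_table(hdr[1], hdr[2], knots, vals)
    i <- i + 1L + n
  }
  out
}

# ---------------------------------------------------------------------------
# system compilation and total energy

# flatten a bd_system + bd_forcefield into the arrays the compiled core
# consumes; bonded term ids resolve per sorted residue pair with generic
# fallback, nonbonded per "nb:X:Y" with "nb:default" fallback
.compile_system <- function(system, ff, constraints_on = FALSE,
                            require_bond_tables = FALSE) {
  stopifnot(inherits(system, "bd_system"), inherits(ff, "bd_forcefield"))
  sz <- .system_sizes(system)
  pos <- system_positions(system)
  n <- nrow(pos)
  chain_id <- rep(seq_along(sz$n), sz$n)
  resi <- unlist(lapply(sz$n, seq_len))
  residue <- unlist(lapply(system$chains, function(c) c$beads$residue))
  charge <- unlist(lapply(system$chains, function(c) c$beads$charge))
  radius <- unlist(lapply(system$chains, function(c) c$beads$radius))

  tab_names <- names(ff$tables)
  tab_id <- setNames(seq_along(ff$tables) - 1L, tab_names)
  kind_of <- vapply(ff$tables, `[[`, character(1), "kind")

  find_tab <- function(keys) {
    for (k in keys) if (k %in% tab_names) return(tab_id[[k]])
    -1L
  }

  # bonds between consecutive beads of each chain
  bonds <- matrix(integer(0), 0, 2)
  bond_target <- numeric(0)
  bond_tab <- integer(0)
  angles <- matrix(integer(0), 0, 3)
  angle_tab <- integer(0)
  dihedrals <- matrix(integer(0), 0, 4)
  dih_tab <- integer(0)
  for (ci in seq_along(system$chains)) {
    nb <- sz$n[ci]
    off <- sz$offset[ci]
    if (nb > 1) {
      i <- off + seq_len(nb - 1) - 1L  # 0-based
      bonds <- rbind(bonds, cbind(i, i + 1L))
      bond_target <- c(bond_target, system$chains[[ci]]$bond_targets)
      bt <- vapply(seq_len(nb - 1), function(k) {
        pair <- sort(residue[off + k + c(0L, 1L)])
        find_tab(c(paste0("bond:", pair[1], ":", pair[2]), "bond"))
      }, integer(1))
      if (require_bond_tables && !constraints_on && any(bt < 0)) {
        stop("no bond table for chain ", ci,
             " and constraints are off; supply a 'bond' table or enable ",
             "constraints", call. = FALSE)
      }
      bond_tab <- c(bond_tab, bt)
    }
    if (nb > 2 && "angle" %in% tab_names) {
      i <- off + seq_len(nb - 2) - 1L
      angles <- rbind(angles, cbind(i, i + 1L, i + 2L))
      angle_tab <- c(angle_tab, rep(tab_id[["angle"]], nb - 2))
    }
    if (nb > 3 && "dihedral" %in% tab_names) {
      i <- off + seq_len(nb - 3) - 1L
      dihedrals <- rbind(dihedrals, cbind(i, i + 1L, i + 2L, i + 3L))
      dih_tab <- c(dih_tab, rep(tab_id[["dihedral"]], nb - 3))
    }
  }

  # nonbonded table per bead pair (by residue type)
  have_nb <- any(kind_of == "nonbonded")
  ntab <- matrix(-1L, n, n)
  if (have_nb) {
    types <- sort(unique(residue))
    type_pair_id <- matrix(-1L, length(types), length(types),
                           dimnames = list(types, types))
    for (a in types) for (b in types) {
      id <- find_tab(c(.nb_key(a, b), "nb:default"))
      if (id < 0) {
        stop("no non-bonded table resolves for pair ", .nb_key(a, b),
             call. = FALSE)
      }
      type_pair_id[a, b] <- id
    }
    ntab <- type_pair_id[residue, residue]
    storage.mode(ntab) <- "integer"
  }

  r <- system$restraints
  restr <- if (nrow(r) > 0) {
    cbind(sz$offset[r$chain_a] + r$bead_a - 1L,
          sz$offset[r$chain_b] + r$bead_b - 1L)
  } else matrix(integer(0), 0, 2)

  list(pos = pos, chain = as.integer(chain_id), resi = as.integer(resi),
       charge = as.numeric(charge), radius = as.numeric(radius),
       bonds = bonds, bond_target = bond_target,
       bond_tab = as.integer(bond_tab),
       angles = angles, angle_tab = as.integer(angle_tab),
       dihedrals = dihedrals, dih_tab = as.integer(dih_tab),
       ntab = ntab, restr = restr,
       restr_cap = as.numeric(r$cap_distance),
       restr_k = as.numeric(r$spring_constant),
       scaling_factor = ff$scaling_factor,
       lambda_d = system$debye_length, dielectric = system$dielectric,
       temperature = system$temperature, viscosity = system$viscosity,
       elec_on = isTRUE(system$electrostatics))
}

.tables_for_cpp <- function(ff) {
  unname(lapply(ff$tables, function(t) {
    list(kind = .table_kinds[[t$kind]], x = t$knots, y = t$values)
  }))
}

#' Total potential energy of a system
#'
#' Sums the bonded spline terms over consecutive tuples, the scaled
#' tabulated non-bonded term s * sum over included pairs, the screened
#' electrostatics over the same pairs, and any restraint energy. Pairs
#' separated by fewer than 3 bonds within a chain are excluded (1-2/1-3
#' exclusion); all cross-chain pairs are included.
#'
#' @param system A `bd_system`.
#' @param ff A `bd_forcefield`.
#' @param include_bond_tables Evaluate bond tables (set `FALSE` to mirror a
#'   constrained run, where constraints replace the bond potential).
#' @return Tibble with columns `term` and `energy` (kcal/mol); terms
#'   `bond`, `angle`, `dihedral`, `nonbonded_table`, `electrostatic`,
#'   `restraint`.
#' @export
total_energy <- function(system, ff, include_bond_tables = TRUE) {
  cs <- .compile_system(system, ff, constraints_on = !include_bond_tables)
  res <- cpp_energy_forces(cs, .tables_for_cpp(ff), include_bond_tables)
  tibble::tibble(
    term = c("bond", "angle", "dihedral", "nonbonded_table",
             "electrostatic", "restraint"),
    energy = c(res$bond, res$angle, res$dihedral, res$nonbonded_table,
               res$electrostatic, res$restraint))
}

#' Forces on every bead
#'
#' Negative gradient of [total_energy()] with the same inclusion rules;
#' mainly for testing and diagnostics.
#'
#' @inheritParams total_energy
#' @return Numeric matrix (beads x 3), kcal/mol/A.
#' @export
system_forces <- function(system, ff, include_bond_tables = TRUE) {
  cs <- .compile_system(system, ff, constraints_on = !include_bond_tables)
  cpp_energy_forces(cs, .tables_for_cpp(ff), include_bond_tables)$forces
}
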