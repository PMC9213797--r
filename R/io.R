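# three-letter <-> one-letter residue codes
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- setNames(names(.aa3to1), .aa3to1)

#' Read a PQR file
#'
#' Parses ATOM/HETATM records of the whitespace (APBS) PQR dialect:
#' record, serial, atom name, residue name, \[chain id,\] residue number,
#' x, y, z, charge, radius. Fixed-column PDB-style lines whose tail carries
#' charge and radius also parse, since tokenization is whitespace-based.
#'
#' @param path File path, or a character vector of lines.
#' @return Tibble with columns `serial`, `atom`, `resname`, `resid`,
#'   `x`, `y`, `z`, `charge`, `radius`.
#' @export
read_pqr <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no ATOM/HETATM records found", call. = FALSE)
  rows <- lapply(idx, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # chain id present when the 5th token is not numeric
    has_chain <- is.na(suppressWarnings(as.numeric(tok[5])))
    need <- if (has_chain) 11L else 10L
    if (length(tok) < need) {
      stop("malformed PQR record at line ", i, ": ", lines[i], call. = FALSE)
    }
    off <- if (has_chain) 1L else 0L
    num <- suppressWarnings(as.numeric(tok[(5 + off):(10 + off)]))
    if (anyNA(num)) {
      stop("non-numeric field in PQR record at line ", i, call. = FALSE)
    }
    list(serial = as.integer(tok[2]), atom = tok[3], resname = tok[4],
         resid = as.integer(num[1]), x = num[2], y = num[3], z = num[4],
         charge = num[5], radius = num[6])
  })
  dplyr::bind_rows(rows)
}

#' Build a bead chain from a PQR structure
#'
#' One bead per residue, positioned at the residue's Calpha atom; the bead
#' charge is the sum of the residue's atomic charges (protonation is
#' whatever the upstream PQR pipeline assigned); the bead radius comes
#' from `radius_table` (a named vector by one-letter code) or `radius`.
#'
#' @param path PQR file path or character lines.
#' @param radius Default bead radius, A.
#' @param radius_table Optional named numeric vector of per-residue-type
#'   radii overriding `radius`.
#' @param name Chain label.
#' @return A `bd_chain`.
#' @export
chain_from_pqr <- function(path, radius = 4.0, radius_table = NULL,
                           name = "pqr_chain") {
  atoms <- read_pqr(path)
  resids <- unique(atoms$resid)
  beads <- lapply(resids, function(rid) {
    at <- atoms[atoms$resid == rid, ]
    ca <- at[at$atom == "CA", ]
    if (nrow(ca) == 0) {
      stop("residue ", rid, " (", at$resname[1], ") has no CA atom",
           call. = FALSE)
    }
    one <- .aa3to1[at$resname[1]]
    if (is.na(one)) {
      stop("unknown residue name '", at$resname[1], "' at residue ", rid,
           call. = FALSE)
    }
    r <- if (!is.null(radius_table) && one %in% names(radius_table)) {
      radius_table[[one]]
    } else radius
    tibble::tibble(residue = unname(one), charge = sum(at$charge),
                   radius = r, x = ca$x[1], y = ca$y[1], z = ca$z[1])
  })
  bd_chain(dplyr::bind_rows(beads), name = name)
}

#' Write a bead chain as a pseudo-PQR file
#'
#' One CA record per bead carrying the bead charge and radius; reading it
#' back with [chain_from_pqr()] reproduces the chain (round trip).
#'
#' @param chain A `bd_chain`.
#' @param path Output path; when `NULL` the lines are returned invisibly.
#' @return The written lines, invisibly.
#' @export
write_chain_pqr <- function(chain, path = NULL) {
  b <- chain$beads
  lines <- sprintf("ATOM %6d  CA %4s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
                   seq_len(nrow(b)), .aa1to3[b$residue], seq_len(nrow(b)),
                   b$x, b$y, b$z, b$charge, b$radius)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Build a bead chain from PDB ATOM records
#'
#' Calpha extraction via [bio3d::read.pdb()]; charges follow the neutral-pH
#' sequence convention (use PQR input when upstream protonation matters).
#'
#' @param path PDB file path.
#' @inheritParams chain_from_pqr
#' @return A `bd_chain`.
#' @export
chain_from_pdb <- function(path, radius = 4.0, name = "pdb_chain") {
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  if (nrow(ca) == 0) stop("no CA atoms in PDB file", call. = FALSE)
  one <- .aa3to1[ca$resid]
  if (anyNA(one)) {
    stop("unknown residue name(s): ",
         paste(unique(ca$resid[is.na(one)]), collapse = ", "), call. = FALSE)
  }
  ch <- .aa_charge_vec()
  bd_chain(tibble::tibble(residue = unname(one), charge = unname(ch[one]),
                          radius = radius, x = ca$x, y = ca$y, z = ca$z),
           name = name)
}

#' Write a trajectory as xyz frames
#'
#' Standard multi-frame xyz: bead count, then a comment line carrying the
#' frame time in ps, then one `<residue> x y z` line per bead. Coordinates
#' are printed with six decimals.
#'
#' @param traj A `bd_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  res <- unlist(lapply(traj$system$chains, function(c) c$beads$residue))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_along(traj$times)) {
    pos <- traj$coords[, , s]
    writeLines(c(as.character(length(res)),
                 sprintf("t= %.6f ps", traj$times[s]),
                 sprintf("%s %.6f %.6f %.6f", res, pos[, 1], pos[, 2],
                         pos[, 3])),
               con)
  }
  invisible(path)
}

#' Read xyz frames
#'
#' @param path Path written by [write_xyz()].
#' @return List with `times` (ps) and `coords` (beads x 3 x frames array),
#'   plus the per-bead labels.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  times <- numeric(0)
  frames <- list()
  labels <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed xyz frame header at line ", i, call. = FALSE)
    t <- as.numeric(sub("^t=\\s*([-0-9.eE+]+).*$", "\\1", lines[i + 1L]))
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    labels <- tok[, 1]
    frames[[length(frames) + 1L]] <-
      matrix(as.numeric(tok[, 2:4]), ncol = 3)
    times <- c(times, t)
    i <- i + 2L + n
  }
  coords <- array(unlist(frames),
                  dim = c(nrow(frames[[1]]), 3, length(frames)))
  list(times = times, coords = coords, labels = labels)
}

#' Write a snapshot as a PDB file
#'
#' One Calpha pseudo-atom per bead (fixed-column ATOM records), chains
#' labelled A, B.
#'
#' @param system A `bd_system` (current coordinates).
#' @param path Output path; `NULL` returns the lines.
#' @return The lines, invisibly.
#' @export
write_pdb_snapshot <- function(system, path = NULL) {
  lines <- character(0)
  serial <- 0L
  for (ci in seq_along(system$chains)) {
    b <- system$chains[[ci]]$beads
    for (i in seq_len(nrow(b))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, .aa1to3[b$residue[i]], LETTERS[ci], i,
        b$x[i], b$y[i], b$z[i]))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
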