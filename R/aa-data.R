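#' Amino-acid property tables
#'
#' Per-residue constants used throughout the package: formal charge at
#' neutral pH (Asp/Glu -1, Lys/Arg +1, His and all others 0, matching the
#' convention under which the (Glu-Lys)25 variants have NCPR 0 and FCR 1),
#' the Kyte-Doolittle hydropathy scale, and membership in the
#' disorder-promoting residue set \{A, R, G, Q, S, P, E, K, D, H\}.
#'
#' @return A tibble with one row per standard residue and columns `aa`
#'   (one-letter code), `charge`, `kd` (Kyte-Doolittle value),
#'   `disorder_promoting` (logical).
#' @examples
#' aa_properties()
#' @export
aa_properties <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  chg <- c(D = -1, E = -1, K = 1, R = 1)
  dis <- c("A", "R", "G", "Q", "S", "P", "E", "K", "D", "H")
  aa <- names(kd)
  tibble::tibble(
    aa = aa,
    charge = unname(ifelse(aa %in% names(chg), chg[aa], 0)),
    kd = unname(kd),
    disorder_promoting = aa %in% dis
  )
}

.aa_alphabet <- function() aa_properties()$aa

.aa_charge_vec <- function() {
  p <- aa_properties()
  setNames(p$charge, p$aa)
}

.aa_kd_vec <- function() {
  p <- aa_properties()
  setNames(p$kd, p$aa)
}

#' Amyloid beta (1-40) sequence
#'
#' One-letter sequence of the Alzheimer amyloid beta peptide, residues 1-40,
#' a 40-residue weak polyampholyte commonly used as a reference disordered
#' sequence (NCPR -0.075, FCR 0.225 under the neutral-pH charge convention).
#'
#' @return A named character scalar.
#' @examples
#' seq_profile(abeta40())
#' @export
abeta40 <- function() {
  c(abeta40 = "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV")
}

# split a one-letter string into validated residue vector
.split_seq <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("sequence must be a single non-empty string", call. = FALSE)
  }
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(res), .aa_alphabet())
  if (length(bad) > 0) {
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res
}
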