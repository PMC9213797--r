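#' (Glu-Lys)25 sequence variants
#'
#' Deterministic generators for the 50-residue polyampholyte family with
#' 25 Glu and 25 Lys: the strictly alternating arrangement (most
#' well-mixed, kappa near 0), the fully segregated diblock (25 E then
#' 25 K, kappa exactly 1), or alternating blocks of length k
#' (`"block_length_k"`, k dividing 25 evenly or the final blocks
#' truncated to keep the 25/25 composition).
#'
#' @param pattern `"alternating"`, `"diblock"`, or `"block_length_k"`
#'   (e.g. `"block_length_5"`).
#' @return A named character scalar (50 residues, 25 E + 25 K).
#' @examples
#' ek_variant("diblock")
#' charge_kappa(ek_variant("diblock"))  # 1
#' @export
ek_variant <- function(pattern = c("alternating", "diblock")) {
  if (grepl("^block_length_\\d+$", pattern[1])) {
    k <- as.integer(sub("block_length_", "", pattern[1]))
    stopifnot(k >= 1, k <= 25)
    res <- character(0)
    lab <- c("E", "K")
    i <- 0L
    while (sum(res == "E") < 25 || sum(res == "K") < 25) {
      want <- lab[i %% 2L + 1L]
      take <- min(k, 25L - sum(res == want))
      res <- c(res, rep(want, take))
      i <- i + 1L
    }
    out <- paste(res, collapse = "")
    names(out) <- pattern[1]
  } else {
    pattern <- match.arg(pattern)
    out <- switch(pattern,
      alternating = paste(rep(c("E", "K"), 25), collapse = ""),
      diblock = paste(c(rep("E", 25), rep("K", 25)), collapse = ""))
    names(out) <- paste0("ek_", pattern)
  }
  n_e <- sum(strsplit(out, "")[[1]] == "E")
  if (n_e != 25 || nchar(out) != 50) {
    stop("pattern does not yield 25 E and 25 K", call. = FALSE)
  }
  out
}

#' Toy PQR fixture
#'
#' Deterministic synthetic PQR text: one Calpha plus one side-chain
#' pseudo-atom per residue along an extended backbone, with random but
#' seed-reproducible atomic charges whose per-residue sums are returned as
#' a ledger. Used to exercise the PQR reader and [chain_from_pqr()]
#' without any external structure.
#'
#' @param n_residues Residue count.
#' @param seed RNG seed; same seed, byte-identical text.
#' @param path Optional output file.
#' @return List with `lines` (PQR text), `sequence` (one-letter),
#'   `residue_charges` (ledger of per-residue sums) and `ca_positions`
#'   (n x 3).
#' @export
toy_pqr <- function(n_residues, seed = 1, path = NULL) {
  stopifnot(n_residues >= 1)
  set.seed(seed)
  aa1 <- sample(.aa_alphabet(), n_residues, replace = TRUE)
  qa <- round(stats::runif(n_residues, -1, 1), 3)
  qb <- round(stats::runif(n_residues, -1, 1), 3)
  ca <- cbind(3.8 * (seq_len(n_residues) - 1), 0, 0)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM %6d  CA %4s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
      serial, .aa1to3[aa1[i]], i, ca[i, 1], ca[i, 2], ca[i, 3], qa[i], 2.0))
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM %6d  CB %4s %5d %11.4f %11.4f %11.4f %8.4f %7.4f",
      serial, .aa1to3[aa1[i]], i, ca[i, 1], ca[i, 2] + 1.5, ca[i, 3],
      qb[i], 2.0))
  }
  if (!is.null(path)) writeLines(lines, path)
  list(lines = lines, sequence = paste(aa1, collapse = ""),
       residue_charges = qa + qb, ca_positions = ca)
}

#' Miniature two-chain association fixture
#'
#' Two synthetic chains in the crosswise starting geometry with the
#' middle-bead restraint: the standard setup for pairwise association
#' runs (15 A separation, 20 A cap by default).
#'
#' @param n Residues per chain.
#' @param charge_pattern `"diblock"`, `"alternating"` (truncated/extended
#'   EK patterns of length n), or `"opposite"` (poly-E vs poly-K, a net
#'   oppositely charged pair).
#' @param separation Middle-bead separation, A.
#' @param cap Restraint cap, A.
#' @param conformation Starting conformation for both chains.
#' @param ... Passed to [two_chain_system()] / [bd_system()].
#' @return A two-chain `bd_system` with one restraint.
#' @export
two_chain_fixture <- function(n = 50, charge_pattern = c("diblock",
                                                         "alternating",
                                                         "opposite"),
                              separation = 15, cap = 20,
                              conformation = "extended", ...) {
  charge_pattern <- match.arg(charge_pattern)
  seqs <- switch(charge_pattern,
    diblock = {
      s <- paste(c(rep("E", ceiling(n / 2)), rep("K", floor(n / 2))),
                 collapse = "")
      c(a = s, b = s)
    },
    alternating = {
      s <- paste(rep_len(c("E", "K"), n), collapse = "")
      c(a = s, b = s)
    },
    opposite = c(a = paste(rep("E", n), collapse = ""),
                 b = paste(rep("K", n), collapse = "")))
  a <- build_chain(seqs[["a"]], conformation, name = "chain_a")
  b <- build_chain(seqs[["b"]], conformation, name = "chain_b")
  two_chain_system(a, b, separation = separation, cap = cap, ...)
}
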