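#' Net charge per residue
#'
#' NCPR = (n+ - n-)/N under the neutral-pH convention (D, E carry -1;
#' K, R carry +1; His and termini neutral). Lies in \[-1, 1\].
#'
#' @param seq One-letter amino-acid string(s); vectorized.
#' @return Numeric vector, one value per sequence.
#' @examples
#' net_charge_per_residue(ek_variant("diblock"))  # 0
#' net_charge_per_residue(abeta40())              # -0.075
#' @export
net_charge_per_residue <- function(seq) {
  vapply(seq, function(s) {
    ch <- .aa_charge_vec()[.split_seq(s)]
    sum(ch) / length(ch)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Fraction of charged residues
#'
#' FCR = (n+ + n-)/N with the same charge convention as
#' [net_charge_per_residue()]. Always >= |NCPR|.
#'
#' @inheritParams net_charge_per_residue
#' @return Numeric vector in \[0, 1\].
#' @export
fraction_charged <- function(seq) {
  vapply(seq, function(s) {
    ch <- .aa_charge_vec()[.split_seq(s)]
    mean(ch != 0)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

# local charge asymmetry of a window/sequence with positive fraction fp and
# negative fraction fm: (fp - fm)^2 / (fp + fm), zero when uncharged
.sigma_asym <- function(fp, fm) {
  tot <- fp + fm
  ifelse(tot == 0, 0, (fp - fm)^2 / tot)
}

# mean squared deviation of window asymmetry from whole-sequence asymmetry
# for blob size g (windows step by one residue, fully inside the sequence)
.delta_g <- function(charges, g) {
  n <- length(charges)
  sig_seq <- .sigma_asym(mean(charges > 0), mean(charges < 0))
  starts <- seq_len(n - g + 1L)
  pos_cum <- cumsum(c(0, charges > 0))
  neg_cum <- cumsum(c(0, charges < 0))
  fp <- (pos_cum[starts + g] - pos_cum[starts]) / g
  fm <- (neg_cum[starts + g] - neg_cum[starts]) / g
  mean((.sigma_asym(fp, fm) - sig_seq)^2)
}

#' Charge segregation measure kappa
#'
#' Measures how blockily the positive and negative charges are arranged,
#' normalized to the maximally segregated arrangement of the same
#' composition: for each blob size g the mean squared deviation of
#' windowed charge asymmetry from the whole-sequence asymmetry
#' (delta_g) is divided by delta_g of the fully segregated rearrangement
#' (negative block, neutral block, positive block), and kappa is the mean
#' of those ratios over the blob sizes, clamped to \[0, 1\]. A strict
#' diblock scores exactly 1; well-mixed arrangements score near 0.
#'
#' @inheritParams net_charge_per_residue
#' @param blob_sizes Window lengths g; default `c(5, 6)`.
#' @return Numeric vector; `NA` for sequences with no charged residues
#'   (kappa undefined).
#' @examples
#' charge_kappa(ek_variant("diblock"))      # 1
#' charge_kappa(ek_variant("alternating"))  # ~0.0009
#' @export
charge_kappa <- function(seq, blob_sizes = c(5, 6)) {
  stopifnot(all(blob_sizes >= 2))
  vapply(seq, function(s) {
    res <- .split_seq(s)
    if (length(res) < max(blob_sizes)) {
      stop("sequence shorter than the largest blob size (",
           max(blob_sizes), ")", call. = FALSE)
    }
    charges <- unname(.aa_charge_vec()[res])
    if (all(charges == 0)) return(NA_real_)
    seg <- sort(charges)  # -1 block, 0 block, +1 block
    ratios <- vapply(blob_sizes, function(g) {
      dmax <- .delta_g(seg, g)
      if (dmax == 0) return(NA_real_)
      .delta_g(charges, g) / dmax
    }, numeric(1))
    min(max(mean(ratios, na.rm = TRUE), 0), 1)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Mean rescaled Kyte-Doolittle hydropathy
#'
#' Mean over residues of (KD value + 4.5), i.e. the Kyte-Doolittle scale
#' shifted onto \[0, 9\] (0 least, 9 most hydrophobic; Ile scores 9,
#' Arg scores 0).
#'
#' @inheritParams net_charge_per_residue
#' @return Numeric vector in \[0, 9\].
#' @export
mean_hydropathy <- function(seq) {
  vapply(seq, function(s) {
    mean(.aa_kd_vec()[.split_seq(s)] + 4.5)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Fraction of disorder-promoting residues
#'
#' Fraction of residues belonging to \{A, R, G, Q, S, P, E, K, D, H\}.
#'
#' @inheritParams net_charge_per_residue
#' @return Numeric vector in \[0, 1\].
#' @export
disorder_fraction <- function(seq) {
  dis <- aa_properties()$aa[aa_properties()$disorder_promoting]
  vapply(seq, function(s) {
    mean(.split_seq(s) %in% dis)
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Das-Pappu phase classification
#'
#' Places a sequence on the Das-Pappu diagram from its positive and
#' negative charged-residue fractions (f+, f-): FCR = f+ + f- < 0.25 is
#' the weak-polyampholyte/globule region; 0.25 <= FCR <= 0.35 the Janus
#' (boundary) region; FCR > 0.35 splits into strong polyampholytes
#' (|NCPR| <= 0.35) and strong polyelectrolytes (|NCPR| > 0.35, one sign
#' dominating).
#'
#' @param seq One-letter amino-acid string(s), or `NULL` if `fplus`/`fminus`
#'   are given directly.
#' @param fplus,fminus Charged-residue fractions per sign; computed from
#'   `seq` when omitted.
#' @return Character vector of region labels.
#' @examples
#' classify_phase(ek_variant("diblock"))  # "Strong polyampholytes"
#' classify_phase(abeta40())              # "Weak polyampholytes"
#' @export
classify_phase <- function(seq = NULL, fplus = NULL, fminus = NULL) {
  if (!is.null(seq)) {
    fr <- lapply(seq, function(s) {
      ch <- .aa_charge_vec()[.split_seq(s)]
      c(mean(ch > 0), mean(ch < 0))
    })
    fplus <- vapply(fr, `[`, numeric(1), 1)
    fminus <- vapply(fr, `[`, numeric(1), 2)
  }
  stopifnot(length(fplus) == length(fminus),
            all(fplus >= 0 & fplus <= 1), all(fminus >= 0 & fminus <= 1))
  fcr <- fplus + fminus
  ncpr <- fplus - fminus
  out <- ifelse(fcr < 0.25, "Weak polyampholytes",
         ifelse(fcr <= 0.35, "Janus sequences",
         ifelse(abs(ncpr) > 0.35, "Strong polyelectrolytes",
                "Strong polyampholytes")))
  if (!is.null(seq) && !is.null(names(seq))) names(out) <- names(seq)
  out
}

#' Charge-pattern profile of one or more sequences
#'
#' One-stop summary of the per-sequence statistics: length, NCPR, FCR,
#' kappa, rescaled hydropathy, disorder fraction and Das-Pappu category,
#' one row per sequence in the column order of the usual CIDER-style table.
#'
#' @param seq Named or unnamed character vector of one-letter sequences.
#' @param blob_sizes Blob sizes passed to [charge_kappa()].
#' @return A tibble with columns `name`, `length`, `ncpr`, `fcr`, `kappa`,
#'   `hydropathy`, `disorder`, `category`.
#' @examples
#' seq_profile(c(ek_variant("diblock"), abeta40()))
#' @export
seq_profile <- function(seq, blob_sizes = c(5, 6)) {
  nm <- names(seq)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seq))
  nm[!nzchar(nm)] <- paste0("seq", which(!nzchar(nm)))
  tibble::tibble(
    name = nm,
    length = vapply(seq, function(s) length(.split_seq(s)), integer(1),
                    USE.NAMES = FALSE),
    ncpr = unname(net_charge_per_residue(seq)),
    fcr = unname(fraction_charged(seq)),
    kappa = unname(charge_kappa(seq, blob_sizes)),
    hydropathy = unname(mean_hydropathy(seq)),
    disorder = unname(disorder_fraction(seq)),
    category = unname(classify_phase(seq))
  )
}

#' Read sequences from FASTA
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector suitable for [seq_profile()] and [build_chain()].
#'
#' @param path FASTA file path.
#' @return Named character vector of one-letter sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}
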