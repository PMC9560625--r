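# Isotope abundances and monoisotopic masses (CODATA/IUPAC values).
ELEMENT_ISOTOPES <- list(
  C = list(mass = c(12.0000000, 13.0033548), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250, 2.0141018), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740, 15.0001089), abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146, 16.9991317, 17.9991596),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.9720712, 32.9714589, 33.9678670, 35.9670812),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# Averagine: the average elemental composition of a peptide per 111.1254 Da
# of monomer mass (Senko-style model), used when the true composition of a
# collagen peptide is not supplied.
AVERAGINE <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
AVERAGINE_MASS <- 111.1254

#' Elemental composition of an averagine pseudo-peptide
#'
#' Scales the averagine monomer to the requested neutral monoisotopic mass,
#' rounds the heavy-element counts, and adjusts the hydrogen count so that the
#' monoisotopic mass of the integer composition is as close as possible to the
#' target.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @return Named integer vector of element counts (C, H, N, O, S).
#' @export
averagine_composition <- function(mass) {
  scale <- mass / AVERAGINE_MASS
  comp <- AVERAGINE * scale
  counts <- c(C = round(comp["C"]), N = round(comp["N"]),
              O = round(comp["O"]), S = round(comp["S"]))
  names(counts) <- c("C", "N", "O", "S")
  mono <- sum(map_dbl(names(counts), ~ ELEMENT_ISOTOPES[[.x]]$mass[1] * counts[[.x]]))
  h <- max(0L, round((mass - mono) / ELEMENT_ISOTOPES$H$mass[1]))
  out <- c(C = counts[["C"]], H = h, N = counts[["N"]],
           O = counts[["O"]], S = counts[["S"]])
  storage.mode(out) <- "integer"
  out
}

# Aggregated (nominal-mass) isotope distribution of one element repeated n
# times, as a vector of probabilities indexed by neutron offset 0, 1, 2, ...
# Computed by repeated polynomial convolution with exponentiation by squaring.
element_distribution <- function(element, n, kmax) {
  iso <- ELEMENT_ISOTOPES[[element]]
  offsets <- round(iso$mass - iso$mass[1])
  base <- numeric(max(offsets) + 1)
  base[offsets + 1] <- iso$abundance
  result <- 1
  p <- base
  while (n > 0) {
    if (n %% 2 == 1) result <- truncate_conv(result, p, kmax)
    n <- n %/% 2
    if (n > 0) p <- truncate_conv(p, p, kmax)
  }
  result
}

truncate_conv <- function(a, b, kmax) {
  out <- convolve_full(a, b)
  head(out, kmax)
}

convolve_full <- function(a, b) {
  la <- length(a); lb <- length(b)
  out <- numeric(la + lb - 1)
  for (i in seq_len(la)) {
    out[i:(i + lb - 1)] <- out[i:(i + lb - 1)] + a[i] * b
  }
  out
}

#' Theoretical isotope envelope of a peptide
#'
#' Returns the relative abundances of the first `k` isotopologues (neutron
#' offsets 0 to k-1), normalised to sum to 1. The distribution is computed by
#' exact convolution of the elemental isotope distributions, either from a
#' supplied elemental composition or from an averagine composition scaled to
#' the peptide's neutral mass. For a singly protonated ion pass
#' `mz - 1.007276` or use [target_peptide()].
#'
#' @param mass Neutral monoisotopic mass in Da, in (700, 3500); ignored when
#'   `composition` is given.
#' @param k Number of isotope positions to return (default 5).
#' @param composition Optional named integer vector of element counts
#'   (subset of C, H, N, O, S).
#' @return Numeric vector of length `k` summing to 1.
#' @examples
#' theoretical_envelope(1104.6)
#' @export
theoretical_envelope <- function(mass = NULL, k = 5, composition = NULL) {
  if (is.null(composition)) {
    if (is.null(mass) || mass <= 700 - PROTON_MASS || mass >= 3500) {
      abort("Peptide mass must lie within the acquisition range (700, 3500).",
            class = "zooms_parameter_error")
    }
    composition <- averagine_composition(mass)
  }
  composition <- composition[composition > 0]
  dist <- 1
  for (el in names(composition)) {
    if (!el %in% names(ELEMENT_ISOTOPES)) {
      abort(sprintf("Unknown element '%s'.", el), class = "zooms_parameter_error")
    }
    dist <- truncate_conv(dist, element_distribution(el, composition[[el]], k), k)
  }
  dist <- c(dist, numeric(max(0, k - length(dist))))[seq_len(k)]
  dist / sum(dist)
}

#' Monoisotopic mass shift of glutamine deamidation
#'
#' The Gln -> Glu conversion replaces a side-chain amide (-NH2) with a
#' carboxyl (-OH): the residue loses one N and one H and gains one O. The
#' shift is computed from standard monoisotopic atomic masses.
#'
#' @return The deamidation mass shift in Da (+0.98402 to five decimals).
#' @export
deamidation_mass_shift <- function() {
  ELEMENT_ISOTOPES$O$mass[1] - ELEMENT_ISOTOPES$N$mass[1] - ELEMENT_ISOTOPES$H$mass[1]
}
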