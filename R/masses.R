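# Residue mass tables for the 20 standard amino acids (Da).
# Average masses drive the gravimetric ug -> mol conversion (bulk peptide
# standards are weighed, so average composition applies); monoisotopic
# masses are kept only for m/z bookkeeping of computed default transitions.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

MONO_RESIDUE_MASS <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)

WATER_MASS_AVG <- 18.0153
WATER_MASS_MONO <- 18.010565
PROTON_MASS <- 1.007276

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop("peptide sequence must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(AVERAGE_RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid residue '%s' at position %d of sequence '%s'",
      chars[bad[1L]], bad[1L], sequence
    ), call. = FALSE)
  }
  chars
}

#' Average molecular mass of a peptide
#'
#' Sums published average residue masses over the sequence and adds one water
#' mass for the free termini. Average (not monoisotopic) masses are used
#' because gravimetric concentrations of synthetic peptide standards refer to
#' bulk material.
#'
#' @param sequence Single uppercase amino-acid string (20 standard residues).
#' @return Average molecular mass in Da.
#' @examples
#' peptide_average_mass("FFVAPFPEVFGK")
#' @export
peptide_average_mass <- function(sequence) {
  chars <- check_sequence(sequence)
  sum(AVERAGE_RESIDUE_MASS[chars]) + WATER_MASS_AVG
}

#' Monoisotopic molecular mass of a peptide
#'
#' Companion to [peptide_average_mass()]; used only as metadata (e.g. when
#' computing default precursor/fragment m/z values), never for gravimetric
#' unit conversion.
#'
#' @inheritParams peptide_average_mass
#' @return Monoisotopic mass in Da.
#' @export
peptide_monoisotopic_mass <- function(sequence) {
  chars <- check_sequence(sequence)
  sum(MONO_RESIDUE_MASS[chars]) + WATER_MASS_MONO
}
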