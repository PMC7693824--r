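#' @keywords internal
"_PACKAGE"

## Reference residue tables used throughout the package. All tables are keyed
## by the 20 standard one-letter residue codes, uppercase.

#' Average (isotope-averaged) residue masses in daltons
#'
#' Masses are for residues in a peptide chain (monomer minus water); a free
#' peptide adds one water ([WATER_MASS]). Average masses, not monoisotopic:
#' the family's printed theoretical masses are isotope-averaged.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
AA_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Mass of one water molecule (average), daltons
#' @export
WATER_MASS <- 18.0153

#' Mass shift of C-terminal amidation (-OH replaced by -NH2), daltons
#'
#' Subtracted from the free-acid mass when the C-terminus is amidated;
#' matches the ~1 u deficit seen between free-acid and amidated forms.
#' @export
AMIDATION_DELTA <- 0.9847

#' Kyte-Doolittle hydropathy scale
#'
#' Used for GRAVY and for the Eisenberg-style hydrophobic moment.
#' @format Named numeric vector over the 20 standard residues.
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Hydrophobic residue set
#'
#' The set used for hydrophobic-fraction percentages and helical-wheel face
#' labels. Together with truncation toward zero this reproduces the family's
#' printed 42% / 52% fractions.
#' @export
HYDROPHOBIC_SET <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' pKa values for ionizable groups (EMBOSS-style)
#'
#' Used by the Henderson-Hasselbalch charge model and the pI solver. `Nterm`
#' and `Cterm` are the free termini; the C-terminal group is dropped when the
#' peptide is amidated.
#' @format Named numeric vector.
#' @export
PKA_SET <- c(
  Cterm = 3.6, D = 3.9, E = 4.1, H = 6.0, Nterm = 8.6,
  K = 10.8, R = 12.5, Y = 10.1, C = 8.5
)

VALID_RESIDUES <- names(AA_MASS_AVG)

#' Validate a peptide sequence
#'
#' Checks that `sequence` is a single non-empty string over the 20 standard
#' one-letter residue codes (uppercase), and returns it split into a
#' character vector of residues.
#'
#' @param sequence Residue string.
#' @param what Label used in error messages.
#' @return Character vector of single residues.
#' @export
check_residues <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop(what, " must be a single non-empty residue string", call. = FALSE)
  }
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), VALID_RESIDUES)
  if (length(bad) > 0L) {
    stop(what, " contains invalid residue letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res
}
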