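# Residue masses (Da) for the 20 canonical amino acids, as residues
# (i.e. minus one water); peptide mass = sum(residues) + H2O.

MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

AVG_RESIDUE_MASS <- c(
  G = 57.05132, A = 71.07794, S = 87.07734, P = 97.11520, V = 99.13106,
  T = 101.10390, C = 103.14290, L = 113.15760, I = 113.15760, N = 114.10270,
  D = 115.08740, Q = 128.12920, K = 128.17240, E = 129.11400, M = 131.19600,
  H = 137.13930, F = 147.17390, R = 156.18570, Y = 163.17330, W = 186.20990
)

WATER_MONO <- 18.010565
WATER_AVG <- 18.015286

#' Peptide mass from a built-in residue-mass table
#'
#' Computes the neutral mass of a peptide as the sum of its residue masses
#' plus one water. Monoisotopic masses are the default; average masses are
#' used for whole-protein molecular weight (see [protein_mw()]).
#'
#' @param sequence Single amino-acid string over the 20 canonical residues.
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")                      # glycine, 75.032 Da
#' peptide_mass("GG") - peptide_mass("G") # one glycine residue, 57.021 Da
#' @export
peptide_mass <- function(sequence, mass_type = c("monoisotopic", "average")) {
  mass_type <- match.arg(mass_type)
  s <- check_sequence(sequence, "peptide sequence")
  chars <- strsplit(s, "")[[1]]
  if (mass_type == "monoisotopic") {
    sum(MONO_RESIDUE_MASS[chars]) + WATER_MONO
  } else {
    sum(AVG_RESIDUE_MASS[chars]) + WATER_AVG
  }
}

#' Protein molecular weight
#'
#' Average (chemical) molecular weight of a protein: sum of average residue
#' masses plus one water.
#'
#' @param sequence Single amino-acid string.
#' @return Molecular weight in Da.
#' @examples
#' protein_mw("GG") # 132.12 Da
#' @export
protein_mw <- function(sequence) {
  peptide_mass(sequence, mass_type = "average")
}
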