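# Amino-acid reference data used across the scan.

#' The 20 standard amino acids, one-letter codes, alphabetical
#'
#' Column order of every propensity matrix and the enumeration order of
#' mutant residues ("the mutant residues lie along the X-axis in
#' alphabetical order").
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter, standard residues
.aa_three_to_one <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

# common modified residues with an unambiguous standard parent
.aa_nonstandard_parent <- c(
  MSE = "M", # selenomethionine
  SEC = "C", # selenocysteine (closest standard parent)
  PYL = "K", # pyrrolysine
  HYP = "P", # hydroxyproline
  SEP = "S", TPO = "T", PTR = "Y", # phosphorylated
  CSO = "C", CME = "C", OCS = "C",
  MLY = "K", M3L = "K", KCX = "K",
  FME = "M"
)

# Kyte-Doolittle hydropathy, kcal-free index units
.aa_hydropathy <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# mean side-chain volumes, cubic Angstrom (Zamyatnin-style residue volumes)
.aa_volume <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6
)

.aa_one_to_three <- setNames(names(.aa_three_to_one), unname(.aa_three_to_one))

.check_aa <- function(x, arg = "amino acid") {
  bad <- setdiff(unique(x), amino_acids())
  if (length(bad) > 0) {
    abort(sprintf("Non-standard %s code(s): %s", arg,
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}
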