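## Chemical reference tables used across the package.

#' Van der Waals radii of heavy elements
#'
#' Fixed element radii (Angstrom) used for solvent-accessible surface area.
#' Hydrogens are ignored throughout (heavy-atom SASA convention).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

## default radius for elements missing from the table
.default_radius <- 1.80

#' Apolar amino acids
#'
#' The nine residues counted as apolar when splitting buried area and
#' classifying residue contacts: A, F, G, I, L, V, M, P, Y.
#'
#' @return Character vector of one-letter codes.
#' @export
apolar_residues <- function() c("A", "F", "G", "I", "L", "V", "M", "P", "Y")

#' Charged amino acids
#'
#' D, E, K, R. Histidine is treated as polar.
#'
#' @return Character vector of one-letter codes.
#' @export
charged_residues <- function() c("D", "E", "K", "R")

#' Chemical class of a residue
#'
#' @param aa One-letter amino acid codes.
#' @return Character vector: "apolar", "charged" or "polar" (NA for unknown).
#' @export
residue_class <- function(aa) {
  out <- rep(NA_character_, length(aa))
  out[aa %in% apolar_residues()] <- "apolar"
  out[aa %in% charged_residues()] <- "charged"
  known <- aa %in% c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")])
  out[known & is.na(out)] <- "polar"
  out
}

## three-letter -> one-letter, standard residues
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

## common nonstandard residues mapped to canonical equivalents
.aa_nonstandard <- c(
  MSE = "M", SEC = "C", CSO = "C", CSS = "C", CME = "C", OCS = "C",
  SEP = "S", TPO = "T", PTR = "Y", PYL = "K", MLY = "K", KCX = "K",
  LLP = "K", HYP = "P", CGU = "E", PCA = "E", FME = "M",
  HSD = "H", HSE = "H", HSP = "H", HIE = "H", HID = "H"
)

#' Maximal per-residue accessible surface area
#'
#' Theoretical maximum ASA (Angstrom^2) of residue X in a Gly-X-Gly
#' tripeptide (Tien et al. 2013, theoretical values), the denominator of
#' relative accessibility.
#'
#' @return Named numeric vector keyed by one-letter code.
#' @export
max_asa_reference <- function() {
  c(
    A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
  )
}

#' Side-chain and terminal pKa values
#'
#' Standard pKa set (EMBOSS values) used by the synthetic titration-curve
#' generator. `nterm`/`cterm` are the free termini.
#'
#' @return Named numeric vector of pKa values.
#' @export
pka_reference <- function() {
  c(
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1,
    nterm = 8.6, cterm = 3.6
  )
}
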