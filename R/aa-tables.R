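# Amino-acid reference tables used across the package.

#' @name aa_tables
#' @title Amino-acid reference data
#' @description Internal lookup tables: one/three-letter codes, Kyte-Doolittle
#'   hydropathy, heavy-atom topology, van der Waals radii, formal charges and
#'   hydrogen-bond donor/acceptor atoms.
#' @keywords internal
NULL

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3
AA3_FROM_1 <- stats::setNames(AA3, AA1)

PAD_TOKEN <- "-"

# Kyte-Doolittle hydropathy index, range [-4.5, 4.5].
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Heavy (non-hydrogen) side-chain atoms beyond CB, as a linear build order.
# Geometry is idealized (tetrahedral chain); adequate for atom counting,
# violation checks and surface construction, not for rotamer realism.
SIDE_CHAIN_ATOMS <- list(
  ALA = character(0),
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CG", "OD1", "ND2"),
  ASP = c("CG", "OD1", "OD2"),
  CYS = c("SG"),
  GLN = c("CG", "CD", "OE1", "NE2"),
  GLU = c("CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CG1", "CG2", "CD1"),
  LEU = c("CG", "CD1", "CD2"),
  LYS = c("CG", "CD", "CE", "NZ"),
  MET = c("CG", "SD", "CE"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CG", "CD"),
  SER = c("OG"),
  THR = c("OG1", "CG2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CG1", "CG2"))

# Heavy atoms per residue: backbone N, CA, C, O (+ CB for non-Gly) + side chain.
heavy_atom_count <- function(res3) {
  base <- ifelse(res3 == "GLY", 4L, 5L)
  base + vapply(SIDE_CHAIN_ATOMS[res3], length, integer(1))
}

# van der Waals radii by element (A).
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2, P = 1.8)

element_of_atom <- function(atom_name) {
  el <- substr(gsub("[0-9]", "", atom_name), 1, 1)
  ifelse(el %in% names(VDW_RADII), el, "C")
}

# Formal charges on representative side-chain atoms (plus termini handled in
# code): Arg/Lys +1, Asp/Glu -1.
FORMAL_CHARGES <- list(
  ARG = c(CZ = 1), LYS = c(NZ = 1), ASP = c(CG = -1), GLU = c(CD = -1))

# Hydrogen-bond donor (+1) and acceptor (-1) heavy atoms by residue.
HBOND_ATOMS <- list(
  ARG = c(NE = 1, NH1 = 1, NH2 = 1),
  ASN = c(ND2 = 1, OD1 = -1),
  ASP = c(OD1 = -1, OD2 = -1),
  GLN = c(NE2 = 1, OE1 = -1),
  GLU = c(OE1 = -1, OE2 = -1),
  HIS = c(ND1 = 1, NE2 = -1),
  LYS = c(NZ = 1),
  SER = c(OG = 1),
  THR = c(OG1 = 1),
  TRP = c(NE1 = 1),
  TYR = c(OH = 1))

aa1_to_aa3 <- function(seq1) {
  letters1 <- strsplit(seq1, "")[[1]]
  bad <- setdiff(letters1, AA1)
  if (length(bad))
    stop("non-standard amino-acid letter(s): ", paste(bad, collapse = ", "))
  unname(AA3_FROM_1[letters1])
}

aa3_to_aa1 <- function(res3) {
  out <- AA1[res3]
  out[is.na(out)] <- "X"
  unname(out)
}
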