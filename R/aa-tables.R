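# Amino-acid lookup tables shared by the builders, the SASA module and
# the energy backend.

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA1 <- structure(names(AA3), names = AA3)

aa_three <- function(one) {
  one <- toupper(one)
  bad <- !one %in% names(AA3)
  if (any(bad)) stop("unknown amino acid letter(s): ",
                     paste(unique(one[bad]), collapse = ", "))
  unname(AA3[one])
}

aa_one <- function(three) {
  three <- toupper(three)
  bad <- !three %in% names(AA1)
  if (any(bad)) stop("unknown residue type(s): ",
                     paste(unique(three[bad]), collapse = ", "))
  unname(AA1[three])
}

## Idealised side-chain templates used by the synthetic generator and
## the extended-monomer builder. Every atom is placed by internal
## coordinates (bond, angle, dihedral) from three named reference atoms;
## dihedrals flagged `chi` are measured relative to chi1 (N-CA-CB-X),
## the single free side-chain dihedral (subsequent dihedrals are held at
## idealised rotamer values, rings are built flat). Heavy-atom counts
## match the real residues so packing and burial see realistic sizes.
## GLY has no side-chain atoms; ALA is CB only.
sc_row <- function(atom, a, b, c, bond, angle, dih, chi = FALSE)
  list(atom = atom, refs = c(a, b, c), bond = bond, angle = angle,
       dih = dih, chi = chi)

SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(),
  SER = list(sc_row("OG", "N", "CA", "CB", 1.42, 110.5, 0, chi = TRUE)),
  CYS = list(sc_row("SG", "N", "CA", "CB", 1.81, 114.0, 0, chi = TRUE)),
  THR = list(sc_row("OG1", "N", "CA", "CB", 1.43, 109.5, 0, chi = TRUE),
             sc_row("CG2", "N", "CA", "CB", 1.52, 111.5, -120, chi = TRUE)),
  VAL = list(sc_row("CG1", "N", "CA", "CB", 1.53, 110.5, 0, chi = TRUE),
             sc_row("CG2", "N", "CA", "CB", 1.53, 110.5, -120, chi = TRUE)),
  PRO = list(sc_row("CG", "N", "CA", "CB", 1.49, 104.5, 0, chi = TRUE),
             sc_row("CD", "CA", "CB", "CG", 1.50, 106.0, 30)),
  LEU = list(sc_row("CG", "N", "CA", "CB", 1.53, 116.3, 0, chi = TRUE),
             sc_row("CD1", "CA", "CB", "CG", 1.52, 110.7, 180),
             sc_row("CD2", "CA", "CB", "CG", 1.52, 110.7, 60)),
  ILE = list(sc_row("CG1", "N", "CA", "CB", 1.53, 110.4, 0, chi = TRUE),
             sc_row("CG2", "N", "CA", "CB", 1.53, 110.5, -120, chi = TRUE),
             sc_row("CD1", "CA", "CB", "CG1", 1.52, 113.9, 180)),
  ASN = list(sc_row("CG", "N", "CA", "CB", 1.52, 112.6, 0, chi = TRUE),
             sc_row("OD1", "CA", "CB", "CG", 1.23, 120.8, 0),
             sc_row("ND2", "CA", "CB", "CG", 1.33, 116.4, 180)),
  ASP = list(sc_row("CG", "N", "CA", "CB", 1.52, 112.6, 0, chi = TRUE),
             sc_row("OD1", "CA", "CB", "CG", 1.25, 118.4, 0),
             sc_row("OD2", "CA", "CB", "CG", 1.25, 118.4, 180)),
  MET = list(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 0, chi = TRUE),
             sc_row("SD", "CA", "CB", "CG", 1.80, 112.7, 180),
             sc_row("CE", "CB", "CG", "SD", 1.79, 100.8, 180)),
  GLN = list(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 0, chi = TRUE),
             sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             sc_row("OE1", "CB", "CG", "CD", 1.23, 120.8, 0),
             sc_row("NE2", "CB", "CG", "CD", 1.33, 116.4, 180)),
  GLU = list(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 0, chi = TRUE),
             sc_row("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             sc_row("OE1", "CB", "CG", "CD", 1.25, 118.4, 0),
             sc_row("OE2", "CB", "CG", "CD", 1.25, 118.4, 180)),
  LYS = list(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 0, chi = TRUE),
             sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             sc_row("CE", "CB", "CG", "CD", 1.52, 111.3, 180),
             sc_row("NZ", "CG", "CD", "CE", 1.49, 111.9, 180)),
  ARG = list(sc_row("CG", "N", "CA", "CB", 1.52, 114.1, 0, chi = TRUE),
             sc_row("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
             sc_row("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
             sc_row("CZ", "CG", "CD", "NE", 1.33, 124.2, 180),
             sc_row("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             sc_row("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = list(sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 0, chi = TRUE),
             sc_row("ND1", "CA", "CB", "CG", 1.38, 122.7, 0),
             sc_row("CD2", "CA", "CB", "CG", 1.36, 131.0, 180),
             sc_row("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
             sc_row("NE2", "CB", "CG", "CD2", 1.37, 107.0, 180)),
  PHE = list(sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 0, chi = TRUE),
             sc_row("CD1", "CA", "CB", "CG", 1.39, 120.8, 0),
             sc_row("CD2", "CA", "CB", "CG", 1.39, 120.8, 180),
             sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             sc_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 0, chi = TRUE),
             sc_row("CD1", "CA", "CB", "CG", 1.39, 120.8, 0),
             sc_row("CD2", "CA", "CB", "CG", 1.39, 120.8, 180),
             sc_row("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             sc_row("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             sc_row("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0),
             sc_row("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 180)),
  TRP = list(sc_row("CG", "N", "CA", "CB", 1.50, 113.8, 0, chi = TRUE),
             sc_row("CD1", "CA", "CB", "CG", 1.37, 127.0, 0),
             sc_row("CD2", "CA", "CB", "CG", 1.43, 126.6, 180),
             sc_row("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180),
             sc_row("CE2", "CB", "CG", "CD2", 1.40, 107.2, 180),
             sc_row("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0),
             sc_row("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
             sc_row("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 180),
             sc_row("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0))
)

## Formal side-chain charges of the surrogate's charged groups and the
## atom(s) whose centroid carries the charge.
CHARGED_GROUPS <- list(
  LYS = list(q = +1, atoms = c("NZ")),
  ARG = list(q = +1, atoms = c("NH1", "NH2", "CZ")),
  ASP = list(q = -1, atoms = c("OD1", "OD2")),
  GLU = list(q = -1, atoms = c("OE1", "OE2"))
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

## First character of a (PDB-style) atom name gives the element for the
## heavy atoms this package handles.
element_from_name <- function(elety) {
  e <- substr(gsub("^[0-9]", "", elety), 1, 1)
  toupper(e)
}
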