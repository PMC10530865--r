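## Shipped per-atom parameter tables.
##
## Van der Waals parameters follow the Amber-derived united-atom convention
## used by polar-hydrogen-only structure preparation: nonpolar hydrogens are
## collapsed into their parent carbon, so carbon carries an enlarged radius.
## R here is the per-atom equilibrium radius R_i (the pair minimum sits at
## R_i + R_j), well depth eps_i in kcal/mol.
.vdw_table <- data.frame(
  element = c("C", "N", "O", "S", "H"),
  radius  = c(2.00, 1.75, 1.60, 2.00, 1.00),
  eps     = c(0.150, 0.160, 0.200, 0.200, 0.020),
  stringsAsFactors = FALSE
)

## Fixed partial-charge template, keyed by (residue, atom name).  The values
## are a deterministic stand-in for tool-assigned partial-equalisation
## charges: magnitudes follow common biomolecular force-field practice and
## every residue sums exactly to its formal charge.  Charges present in an
## input file (mol2) always take precedence over this template.

# Backbone of a non-terminal residue (sums to 0).
.bb_charges <- c(N = -0.35, H = 0.25, HN = 0.25, CA = 0.10, C = 0.60, O = -0.60)

# Side-chain charges per residue (sum = formal side-chain charge).
.sc_charges <- list(
  ALA = c(CB = 0),
  GLY = c()[0],
  SER = c(CB = 0.15, OG = -0.55, HG = 0.40),
  THR = c(CB = 0.15, OG1 = -0.55, HG1 = 0.40, CG2 = 0),
  CYS = c(CB = 0.12, SG = -0.32, HG = 0.20),
  VAL = c(CB = 0, CG1 = 0, CG2 = 0),
  LEU = c(CB = 0, CG = 0, CD1 = 0, CD2 = 0),
  ILE = c(CB = 0, CG1 = 0, CG2 = 0, CD1 = 0),
  MET = c(CB = 0, CG = 0.06, SD = -0.12, CE = 0.06),
  PRO = c(CB = 0, CG = 0, CD = 0.10),
  PHE = c(CB = 0, CG = 0, CD1 = 0, CD2 = 0, CE1 = 0, CE2 = 0, CZ = 0),
  TYR = c(CB = 0, CG = 0, CD1 = 0, CD2 = 0, CE1 = 0, CE2 = 0,
          CZ = 0.15, OH = -0.55, HH = 0.40),
  TRP = c(CB = 0, CG = 0, CD1 = 0.10, NE1 = -0.40, HE1 = 0.35,
          CD2 = 0, CE2 = -0.05, CE3 = 0, CZ2 = 0, CZ3 = 0, CH2 = 0),
  HIS = c(CB = 0, CG = 0.10, ND1 = -0.40, HD1 = 0.35, CD2 = 0.10,
          CE1 = 0.20, NE2 = -0.35),
  ASP = c(CB = -0.10, CG = 0.50, OD1 = -0.70, OD2 = -0.70),
  GLU = c(CB = 0, CG = -0.10, CD = 0.50, OE1 = -0.70, OE2 = -0.70),
  ASN = c(CB = 0, CG = 0.55, OD1 = -0.55, ND2 = -0.60,
          HD21 = 0.30, HD22 = 0.30),
  GLN = c(CB = 0, CG = 0, CD = 0.55, OE1 = -0.55, NE2 = -0.60,
          HE21 = 0.30, HE22 = 0.30),
  LYS = c(CB = 0, CG = 0, CD = 0, CE = 0.25, NZ = -0.30,
          HZ1 = 0.35, HZ2 = 0.35, HZ3 = 0.35),
  ARG = c(CB = 0, CG = 0, CD = 0.10, NE = -0.40, HE = 0.35, CZ = 0.55,
          NH1 = -0.50, HH11 = 0.35, HH12 = 0.35,
          NH2 = -0.50, HH21 = 0.35, HH22 = 0.35),
  # Trimethylated lysine: quaternary amine, +1 spread over the methyls.
  M3K = c(CB = 0, CG = 0, CD = 0, CE = 0.25, NZ = -0.30,
          CM1 = 0.35, CM2 = 0.35, CM3 = 0.35)
)

# Proline backbone has no amide hydrogen; N absorbs its charge.
.pro_bb_charges <- c(N = -0.10, CA = 0.10, C = 0.60, O = -0.60)

# Terminal and cap variants (each block sums to 0):
#  - neutral N-terminal amine replaces N/HN of the backbone template,
#  - neutral C-terminal carboxylic acid replaces C/O,
#  - acetyl and N-methyl-amide capping groups.
## N/H1/H2 sum to -0.10, matching the N/HN sum they replace, so a neutral
## residue stays neutral at the N-terminus.
.nterm_charges <- c(N = -0.80, H1 = 0.35, H2 = 0.35)
.cterm_charges <- c(C = 0.55, O = -0.50, OXT = -0.45, HXT = 0.40)
.cap_charges <- list(
  ACE = c(CH3 = 0.00, C = 0.60, O = -0.60),
  NME = c(N = -0.35, H = 0.25, HN = 0.25, CH3 = 0.10)
)

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.standard_residues <- c(unname(.aa3), "M3K")

typing_error <- function(msg) {
  stop(errorCondition(msg, class = c("seedgrow_typing_error", "error")))
}

## Look up the template charge of one atom.  `position` is "internal",
## "nterm" or "cterm"; cap residues ACE/NME have their own tables.
template_charge <- function(resname, atom_name, position = "internal") {
  if (resname %in% names(.cap_charges)) {
    q <- .cap_charges[[resname]][atom_name]
    if (is.na(q)) typing_error(sprintf("no charge template for %s/%s",
                                       resname, atom_name))
    return(unname(q))
  }
  if (!resname %in% .standard_residues)
    typing_error(sprintf("unknown residue '%s'", resname))
  bb <- if (resname == "PRO") .pro_bb_charges else .bb_charges
  if (position == "nterm" && atom_name %in% names(.nterm_charges))
    return(unname(.nterm_charges[atom_name]))
  if (position == "cterm" && atom_name %in% names(.cterm_charges))
    return(unname(.cterm_charges[atom_name]))
  if (atom_name %in% names(bb)) return(unname(bb[atom_name]))
  sc <- .sc_charges[[resname]]
  if (!is.null(sc) && atom_name %in% names(sc)) return(unname(sc[atom_name]))
  typing_error(sprintf("no charge template for %s/%s", resname, atom_name))
}

vdw_for_element <- function(element) {
  i <- match(element, .vdw_table$element)
  if (anyNA(i)) {
    bad <- unique(element[is.na(i)])
    typing_error(sprintf("no van der Waals parameters for element(s): %s",
                         paste(bad, collapse = ", ")))
  }
  list(radius = .vdw_table$radius[i], eps = .vdw_table$eps[i])
}
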