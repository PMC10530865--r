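## Residue topology templates: ideal internal coordinates for side-chain
## construction in the polar-hydrogen-only representation (heavy atoms plus
## hydrogens on N/O/S).  Each entry places one atom by NeRF from three
## reference atoms of the same residue: torsion r1-r2-r3-atom, bond angle
## r2-r3-atom (deg), bond r3-atom (Angstrom).  `dihedral` is either a fixed
## value or list(chi = k, offset = deg) meaning rotameric torsion chi_k plus
## a rigid branch offset.

sc_atom <- function(name, r1, r2, r3, bond, angle, dihedral) {
  list(name = name, refs = c(r1, r2, r3), bond = bond, angle = angle,
       dihedral = dihedral)
}
chi <- function(k, offset = 0) list(chi = k, offset = offset)

## Ideal backbone internal coordinates.
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_c_n_h = 119.3, omega = 180
)

## The L-configuration branch improper: torsion N-C-CA-CB.
.cb_improper <- -122.6
.cb_entry <- sc_atom("CB", "N", "C", "CA", 1.530, 110.5, .cb_improper)

.sidechain_topology <- list(
  GLY = list(),
  ALA = list(.cb_entry),
  SER = list(.cb_entry,
             sc_atom("OG",  "N", "CA", "CB", 1.417, 110.8, chi(1)),
             sc_atom("HG",  "CA", "CB", "OG", 0.960, 108.5, 180)),
  CYS = list(.cb_entry,
             sc_atom("SG",  "N", "CA", "CB", 1.808, 113.8, chi(1)),
             sc_atom("HG",  "CA", "CB", "SG", 1.340, 96.0, 180)),
  THR = list(.cb_entry,
             sc_atom("OG1", "N", "CA", "CB", 1.433, 109.6, chi(1)),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi(1, -122)),
             sc_atom("HG1", "CA", "CB", "OG1", 0.960, 108.5, 180)),
  VAL = list(.cb_entry,
             sc_atom("CG1", "N", "CA", "CB", 1.521, 110.5, chi(1)),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi(1, 122))),
  LEU = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.530, 116.3, chi(1)),
             sc_atom("CD1", "CA", "CB", "CG", 1.521, 110.7, chi(2)),
             sc_atom("CD2", "CA", "CB", "CG", 1.521, 110.7, chi(2, 122))),
  ILE = list(.cb_entry,
             sc_atom("CG1", "N", "CA", "CB", 1.530, 110.4, chi(1)),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi(1, -122)),
             sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.8, chi(2))),
  MET = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi(1)),
             sc_atom("SD",  "CA", "CB", "CG", 1.803, 112.7, chi(2)),
             sc_atom("CE",  "CB", "CG", "SD", 1.791, 100.9, chi(3))),
  PRO = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.492, 104.5, 30),
             sc_atom("CD",  "CA", "CB", "CG", 1.503, 106.1, -35)),
  PHE = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.502, 113.8, chi(1)),
             sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.8, chi(2)),
             sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.8, chi(2, 180)),
             sc_atom("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.372, 120.0, 0)),
  TYR = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.502, 113.8, chi(1)),
             sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.8, chi(2)),
             sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.8, chi(2, 180)),
             sc_atom("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.372, 120.0, 0),
             sc_atom("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, 180),
             sc_atom("HH",  "CE1", "CZ", "OH", 0.960, 109.0, 0)),
  TRP = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.498, 113.6, chi(1)),
             sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, chi(2)),
             sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.6, chi(2, 180)),
             sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
             sc_atom("HE1", "CG", "CD1", "NE1", 1.010, 125.0, 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
             sc_atom("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
             sc_atom("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
             sc_atom("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
             sc_atom("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  HIS = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.504, 113.8, chi(1)),
             sc_atom("ND1", "CA", "CB", "CG", 1.378, 122.7, chi(2)),
             sc_atom("CD2", "CA", "CB", "CG", 1.356, 131.2, chi(2, 180)),
             sc_atom("CE1", "CB", "CG", "ND1", 1.321, 109.0, 180),
             sc_atom("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180),
             sc_atom("HD1", "CD2", "CG", "ND1", 1.010, 126.0, 180)),
  ASP = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi(1)),
             sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.4, chi(2)),
             sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.4, chi(2, 180))),
  ASN = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi(1)),
             sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, chi(2)),
             sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.4, chi(2, 180)),
             sc_atom("HD21", "CB", "CG", "ND2", 1.010, 120.0, 0),
             sc_atom("HD22", "CB", "CG", "ND2", 1.010, 120.0, 180)),
  GLU = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi(1)),
             sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi(2)),
             sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.4, chi(3)),
             sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.4, chi(3, 180))),
  GLN = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi(1)),
             sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi(2)),
             sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, chi(3)),
             sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.4, chi(3, 180)),
             sc_atom("HE21", "CG", "CD", "NE2", 1.010, 120.0, 0),
             sc_atom("HE22", "CG", "CD", "NE2", 1.010, 120.0, 180)),
  LYS = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi(1)),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi(2)),
             sc_atom("CE",  "CB", "CG", "CD", 1.508, 111.3, chi(3)),
             sc_atom("NZ",  "CG", "CD", "CE", 1.489, 111.5, chi(4)),
             sc_atom("HZ1", "CD", "CE", "NZ", 1.010, 109.5, 60),
             sc_atom("HZ2", "CD", "CE", "NZ", 1.010, 109.5, -60),
             sc_atom("HZ3", "CD", "CE", "NZ", 1.010, 109.5, 180)),
  M3K = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi(1)),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi(2)),
             sc_atom("CE",  "CB", "CG", "CD", 1.508, 111.3, chi(3)),
             sc_atom("NZ",  "CG", "CD", "CE", 1.511, 111.5, chi(4)),
             sc_atom("CM1", "CD", "CE", "NZ", 1.498, 109.5, 60),
             sc_atom("CM2", "CD", "CE", "NZ", 1.498, 109.5, -60),
             sc_atom("CM3", "CD", "CE", "NZ", 1.498, 109.5, 180)),
  ARG = list(.cb_entry,
             sc_atom("CG",  "N", "CA", "CB", 1.530, 114.1, chi(1)),
             sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi(2)),
             sc_atom("NE",  "CB", "CG", "CD", 1.461, 112.0, chi(3)),
             sc_atom("CZ",  "CG", "CD", "NE", 1.329, 124.2, chi(4)),
             sc_atom("HE",  "CG", "CD", "NE", 1.010, 118.0, chi(4, 180)),
             sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180),
             sc_atom("HH11", "NE", "CZ", "NH1", 1.010, 120.0, 0),
             sc_atom("HH12", "NE", "CZ", "NH1", 1.010, 120.0, 180),
             sc_atom("HH21", "NE", "CZ", "NH2", 1.010, 120.0, 0),
             sc_atom("HH22", "NE", "CZ", "NH2", 1.010, 120.0, 180))
)

## Number of rotameric chi torsions per residue type.
.n_chi <- c(GLY = 0, ALA = 0, SER = 1, CYS = 1, THR = 1, VAL = 1, PRO = 0,
            LEU = 2, ILE = 2, PHE = 2, TYR = 2, TRP = 2, HIS = 2, ASP = 2,
            ASN = 2, MET = 3, GLU = 3, GLN = 3, LYS = 4, ARG = 4, M3K = 4)

## Backbone-independent rotamer states for chi torsions: anti, gauche-,
## gauche+ with prior weights; chi selection is sampled during growing and
## fixed to anti for the deterministic extended builder.
.chi_states <- c(180, -60, 60)
.chi_weights <- c(0.45, 0.35, 0.20)

residue_elements <- function(names) {
  ## First non-digit character of a PDB atom name gives the element for
  ## standard amino-acid atoms (we never add nonpolar H, so no 2-letter
  ## ambiguity beyond S/O/N/C/H here).
  substr(gsub("^[0-9]+", "", names), 1, 1)
}
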