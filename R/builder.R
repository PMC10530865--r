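## Ideal-geometry peptide construction.  Backbones are chained with NeRF
## placement from ideal bond lengths/angles; side chains come from the
## topology templates with rotameric chi torsions.  These primitives are
## shared by the fragment builder, the fixture generator and the growing
## engine.

## Side-chain coordinates for one residue given its backbone N/CA/C.
## `chis`: numeric vector of chi values (degrees), recycled as needed.
sidechain_xyz <- function(restype, N, CA, C, chis = 180) {
  topo <- .sidechain_topology[[restype]]
  if (is.null(topo))
    typing_error(sprintf("unsupported residue type '%s'", restype))
  pos <- list(N = N, CA = CA, C = C)
  nchi <- .n_chi[[restype]]
  chis <- rep_len(chis, max(1, nchi))
  for (entry in topo) {
    dih <- entry$dihedral
    if (is.list(dih)) dih <- chis[dih$chi] + dih$offset
    refs <- pos[entry$refs]
    pos[[entry$name]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                    entry$bond, entry$angle, dih)
  }
  pos[setdiff(names(pos), c("N", "CA", "C"))]
}

## Backbone + side chain of residue i placed C-ward of residue i-1.
## Returns xyz list: HN (unless PRO), N, CA, C and side-chain atoms, plus
## the O of the *previous* residue (determined by psi_prev).
forward_residue_xyz <- function(prevN, prevCA, prevC, psi_prev, phi,
                                restype, chis = 180, omega = 180) {
  g <- .bb_geom
  N <- place_atom(prevN, prevCA, prevC, g$c_n, g$ang_ca_c_n, psi_prev)
  CA <- place_atom(prevCA, prevC, N, g$n_ca, g$ang_c_n_ca, omega)
  C <- place_atom(prevC, N, CA, g$ca_c, g$ang_n_ca_c, phi)
  O_prev <- place_atom(prevN, prevCA, prevC, g$c_o, g$ang_ca_c_o,
                       psi_prev + 180)
  out <- list(N = N, CA = CA, C = C)
  if (restype != "PRO")
    out$HN <- place_atom(prevCA, prevC, N, g$n_h, g$ang_c_n_h, 0)
  c(out, sidechain_xyz(restype, N, CA, C, chis), list(O_prev = O_prev))
}

## Backbone + side chain of residue i placed N-ward of residue i+1.
## psi is the psi torsion of residue i; phi_next belongs to residue i+1.
## Also returns HN_next, the amide hydrogen of residue i+1 (which becomes
## placeable once C(i) exists).
backward_residue_xyz <- function(nextN, nextCA, nextC, phi_next, psi,
                                 restype, chis = 180) {
  g <- .bb_geom
  C <- place_atom(nextC, nextCA, nextN, g$c_n, g$ang_c_n_ca, phi_next)
  CA <- place_atom(nextCA, nextN, C, g$ca_c, g$ang_ca_c_n, 180)
  N <- place_atom(nextN, C, CA, g$n_ca, g$ang_n_ca_c, psi)
  O <- place_atom(nextCA, nextN, C, g$c_o, 123.0, 0)
  HN_next <- place_atom(CA, C, nextN, g$n_h, g$ang_c_n_h, 0)
  c(list(N = N, CA = CA, C = C, O = O, HN_next = HN_next),
    sidechain_xyz(restype, N, CA, C, chis))
}

## Assemble a pepstruct from a list of per-residue atom-position lists.
## `entries`: list of list(resno, resid, atoms = named list of xyz).
assemble_structure <- function(entries, chain = "P") {
  rows <- list()
  for (e in entries) {
    for (nm in names(e$atoms)) {
      xyz <- e$atoms[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        serial = NA_integer_, name = nm,
        element = residue_elements(nm),
        resid = e$resid, chain = chain, resno = e$resno,
        x = xyz[1], y = xyz[2], z = xyz[3],
        charge = NA_real_, radius = NA_real_, eps = NA_real_,
        is_h = substr(nm, 1, 1) == "H", stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$serial <- seq_len(nrow(df))
  new_pepstruct(df)
}

## Canonical within-residue atom order for assembled models.
.atom_order <- c("N", "H1", "H2", "HN", "CA", "CB", "CG", "CG1", "CG2",
                 "OG", "OG1", "HG", "HG1", "SG", "CD", "CD1", "CD2", "SD",
                 "OD1", "OD2", "ND1", "ND2", "HD1", "HD21", "HD22", "CE",
                 "CE1", "CE2", "CE3", "NE", "NE1", "NE2", "OE1", "OE2",
                 "HE", "HE1", "HE21", "HE22", "NZ", "HZ1", "HZ2", "HZ3",
                 "CM1", "CM2", "CM3", "CZ", "CZ2", "CZ3", "CH2", "NH1",
                 "NH2", "HH", "HH11", "HH12", "HH21", "HH22", "OH",
                 "CH3", "C", "O", "OXT", "HXT")

order_atoms <- function(s) {
  res <- residues(s)
  key <- match(paste(s$chain, s$resno), paste(res$chain, res$resno))
  ord <- order(key, match(s$name, .atom_order))
  s <- s[ord, , drop = FALSE]
  s$serial <- seq_len(nrow(s))
  rownames(s) <- NULL
  s
}

#' Build a peptide in an ideal-geometry conformation
#'
#' Constructs an all-atom (polar-hydrogen) model of a peptide with ideal
#' bond lengths and angles.  Backbone torsions default to an extended
#' conformation (phi = -120, psi = 120, omega = 180); side-chain chi
#' torsions default to anti (180).  Optional acetyl (`ACE`) and
#' N-methyl-amide (`NME`) capping groups block the cut termini; an uncapped
#' N-terminus is built as a neutral amine and an uncapped C-terminus as a
#' neutral carboxylic acid.
#'
#' @param res3 character vector of 3-letter residue codes (supports the 20
#'   standard amino acids plus `M3K`, trimethyl-lysine).
#' @param phi,psi backbone torsions in degrees, recycled over residues.
#' @param chis side-chain chi torsions in degrees, recycled.
#' @param n_cap `"none"` or `"acetyl"`.
#' @param c_cap `"none"` or `"nme"`.
#' @param start_resno residue number of the first real residue.
#' @param chain chain identifier.
#' @return an unparameterised `pepstruct` (see [assign_parameters()]).
#' @export
build_peptide <- function(res3, phi = -120, psi = 120, chis = 180,
                          n_cap = c("none", "acetyl"),
                          c_cap = c("none", "nme"),
                          start_resno = 1, chain = "P") {
  n_cap <- match.arg(n_cap)
  c_cap <- match.arg(c_cap)
  n <- length(res3)
  stopifnot(n >= 1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  if (!is.list(chis)) chis <- rep_len(list(chis), n)
  g <- .bb_geom
  entries <- list()

  ## seed frame: first three mainchain atoms laid in the xy-plane
  if (n_cap == "acetyl") {
    CH3 <- c(0, 0, 0)
    Cc <- c(1.509, 0, 0)
    Oc <- place_flat(CH3, Cc, g$c_o, 120.8, flip = TRUE)
    ## first residue N from the cap carbonyl
    N1 <- place_flat(CH3, Cc, g$c_n, g$ang_ca_c_n)
    cap_atoms <- list(CH3 = CH3, C = Cc, O = Oc)
    entries[[1]] <- list(resno = start_resno - 1, resid = "ACE",
                         atoms = cap_atoms)
    prev <- list(N = CH3, CA = Cc, C = N1)  # pseudo-frame for residue 1
    ## residue 1 backbone continues from the cap
    CA1 <- place_atom(CH3, Cc, N1, g$n_ca, g$ang_c_n_ca, 180)
    C1 <- place_atom(Cc, N1, CA1, g$ca_c, g$ang_n_ca_c, phi[1])
    HN1 <- if (res3[1] != "PRO")
      place_atom(CH3, Cc, N1, g$n_h, g$ang_c_n_h, 0) else NULL
    atoms1 <- list(N = N1, CA = CA1, C = C1)
    if (!is.null(HN1)) atoms1$HN <- HN1
  } else {
    N1 <- c(0, 0, 0)
    CA1 <- c(g$n_ca, 0, 0)
    C1 <- place_flat(N1, CA1, g$ca_c, g$ang_n_ca_c)
    atoms1 <- list(N = N1, CA = CA1, C = C1)
    if (res3[1] != "PRO") {
      atoms1$H1 <- place_atom(C1, CA1, N1, 1.01, 109.5, 60)
      atoms1$H2 <- place_atom(C1, CA1, N1, 1.01, 109.5, 180)
    }
  }
  atoms1 <- c(atoms1, sidechain_xyz(res3[1], atoms1$N, atoms1$CA, atoms1$C,
                                    chis[[1]]))
  entries[[length(entries) + 1]] <- list(resno = start_resno,
                                         resid = res3[1], atoms = atoms1)
  prev <- list(N = atoms1$N, CA = atoms1$CA, C = atoms1$C)
  prev_idx <- length(entries)

  for (i in seq_len(n)[-1]) {
    at <- forward_residue_xyz(prev$N, prev$CA, prev$C, psi[i - 1], phi[i],
                              res3[i], chis[[i]])
    entries[[prev_idx]]$atoms$O <- at$O_prev
    at$O_prev <- NULL
    entries[[length(entries) + 1]] <- list(resno = start_resno + i - 1,
                                           resid = res3[i], atoms = at)
    prev <- list(N = at$N, CA = at$CA, C = at$C)
    prev_idx <- length(entries)
  }

  ## C-terminal treatment
  if (c_cap == "nme") {
    Nc <- place_atom(prev$N, prev$CA, prev$C, g$c_n, g$ang_ca_c_n, psi[n])
    entries[[prev_idx]]$atoms$O <-
      place_atom(prev$N, prev$CA, prev$C, g$c_o, g$ang_ca_c_o, psi[n] + 180)
    CH3c <- place_atom(prev$CA, prev$C, Nc, 1.458, g$ang_c_n_ca, 180)
    HNc <- place_atom(prev$CA, prev$C, Nc, g$n_h, g$ang_c_n_h, 0)
    entries[[length(entries) + 1]] <- list(resno = start_resno + n,
                                           resid = "NME",
                                           atoms = list(N = Nc, HN = HNc,
                                                        CH3 = CH3c))
  } else {
    O <- place_atom(prev$N, prev$CA, prev$C, g$c_o, g$ang_ca_c_o,
                    psi[n] + 180)
    OXT <- place_atom(prev$N, prev$CA, prev$C, 1.252, 117.0, psi[n])
    HXT <- place_atom(prev$CA, prev$C, OXT, 0.96, 109.0, 180)
    entries[[prev_idx]]$atoms$O <- O
    entries[[prev_idx]]$atoms$OXT <- OXT
    entries[[prev_idx]]$atoms$HXT <- HXT
  }
  order_atoms(assemble_structure(entries, chain = chain))
}

## Place a third atom in the xy-plane given two previous positions.
place_flat <- function(a, b, bond, angle, flip = FALSE) {
  th <- deg2rad(180 - angle)
  dir <- unit(b - a)
  perp <- c(-dir[2], dir[1], 0)
  if (flip) perp <- -perp
  b + bond * (cos(pi - deg2rad(angle)) * dir + sin(pi - deg2rad(angle)) * perp)
}
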