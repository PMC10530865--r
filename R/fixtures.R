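## Synthetic planted-truth fixtures: toy receptor-peptide complexes whose
## bound peptide conformation is known by construction, so that docking,
## growing, scoring and evaluation can be exercised end-to-end without any
## external structure downloads.  The receptors emulate the binding pattern
## of shallow peptide-reader pockets: a dense contact shell around the
## first two peptide residues (the anchor), sparser surface contacts under
## residues 3-5, and nothing beyond, so that the per-residue interaction
## energy is dominated by the N-terminal anchor.

## N-terminal tail sequence of histone H3, used as the default fixture
## peptide.
.h3_tail <- "ARTKQTARKSTGGKA"

#' Generate a synthetic receptor-peptide complex with planted ground truth
#'
#' Builds an ideal-geometry extended peptide (the first `n_res` residues of
#' the histone H3 tail), then surrounds its first two residues with a shell
#' of neutral carbon pseudo-atoms (alanine C-beta) at van der Waals contact
#' distance, places a few oxygen pseudo-atoms (serine O-gamma, carrying the
#' template's negative partial charge) next to the peptide's charged
#' nitrogen groups, and adds a sparse contact floor under residues 3-5.
#' All receptor atoms are standard-residue pseudo-atoms, so the shipped
#' parameter table applies unchanged.  The planted pose is clash-free
#' against the receptor at clash factor 0.7 by construction.
#'
#' @param n_res peptide length, 5 to 15 residues.
#' @param rng_seed integer seed; the same seed reproduces the same complex.
#' @param shell_tries direction samples per anchor atom for the contact
#'   shell.
#' @return object of class `planted_complex`: list with `target` and
#'   `peptide` (parameterised `pepstruct`s), `sequence`
#'   (a [peptide_sequence()]), `seed_window` (a `fragment_spec`, start 1)
#'   and `rng_seed`.
#' @export
make_planted_complex <- function(n_res = 6, rng_seed = 1,
                                 shell_tries = 40) {
  stopifnot(n_res >= 5, n_res <= 15)
  set.seed(rng_seed)
  seq <- peptide_sequence(substr(.h3_tail, 1, n_res))
  pep <- assign_parameters(build_peptide(seq_res3(seq)))
  pep_h <- heavy(pep)
  pxyz <- coords(pep_h)

  accept <- function(pos, placed) {
    if (min(dist2_matrix(matrix(pos, 1), pxyz)) < 3.4^2) return(FALSE)
    if (!is.null(placed) &&
        min(dist2_matrix(matrix(pos, 1), placed)) < 2.0^2) return(FALSE)
    TRUE
  }

  placed <- NULL
  kinds <- character(0)
  add <- function(pos, kind) {
    placed <<- rbind(placed, pos)
    kinds <<- c(kinds, kind)
  }

  ## pocket opening direction: the peptide's smallest principal axis; the
  ## receptor is built on the opposite side, giving a concave one-sided
  ## cradle the peptide rests in (a groove, not a cage)
  pc <- svd(scale(pxyz, scale = FALSE))$v
  nvec <- pc[, 3]
  pocket_dir <- function() {
    repeat {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      if (sum(dir * nvec) > 0.25) return(dir)
    }
  }

  ## contact cradle under the heavy atoms of residues 1-2
  anchor <- pxyz[pep_h$resno <= 2, , drop = FALSE]
  for (i in seq_len(nrow(anchor))) {
    for (k in seq_len(shell_tries)) {
      pos <- anchor[i, ] + pocket_dir() * stats::runif(1, 3.6, 4.6)
      if (accept(pos, placed)) add(pos, "C")
    }
  }

  ## negatively charged oxygens opposite the peptide's cationic nitrogens
  cat_n <- pep[pep$resno <= 2 &
                 pep$name %in% c("N", "NZ", "NH1", "NH2", "NE"), ,
               drop = FALSE]
  for (i in seq_len(nrow(cat_n))) {
    npos <- c(cat_n$x[i], cat_n$y[i], cat_n$z[i])
    for (k in seq_len(12)) {
      pos <- npos + pocket_dir() * 3.5
      if (accept(pos, placed)) { add(pos, "O"); break }
    }
  }

  ## second, outer layer behind the contact cradle (receptor interior)
  for (i in seq_len(nrow(anchor))) {
    for (k in seq_len(shell_tries %/% 2)) {
      pos <- anchor[i, ] + pocket_dir() * stats::runif(1, 5.8, 7.2)
      if (accept(pos, placed)) add(pos, "C")
    }
  }

  ## thinner groove wall continuing along residue 3
  wall <- pxyz[pep_h$resno == 3, , drop = FALSE]
  for (i in seq_len(nrow(wall))) {
    for (k in seq_len(shell_tries %/% 3)) {
      pos <- wall[i, ] + pocket_dir() * stats::runif(1, 3.8, 4.8)
      if (accept(pos, placed)) add(pos, "C")
    }
  }

  ## sparse contact floor under residues 3..min(5, n_res), same side
  ca <- pep_h[pep_h$name == "CA" &
                pep_h$resno >= 3 & pep_h$resno <= min(5, n_res), ,
              drop = FALSE]
  for (i in seq_len(nrow(ca))) {
    base <- c(ca$x[i], ca$y[i], ca$z[i])
    hits <- 0
    for (k in seq_len(16)) {
      pos <- base + nvec * stats::runif(1, 3.8, 5.0) +
        stats::rnorm(3, 0, 0.8)
      if (accept(pos, placed)) { add(pos, "C"); hits <- hits + 1 }
      if (hits >= 3) break
    }
  }

  tgt <- new_pepstruct(data.frame(
    serial = seq_len(nrow(placed)),
    name = ifelse(kinds == "O", "OG", "CB"),
    element = kinds,
    resid = ifelse(kinds == "O", "SER", "ALA"),
    chain = "T", resno = seq_len(nrow(placed)),
    x = placed[, 1], y = placed[, 2], z = placed[, 3],
    charge = NA_real_, radius = NA_real_, eps = NA_real_,
    is_h = FALSE, stringsAsFactors = FALSE))
  tgt <- assign_parameters(tgt)

  structure(list(target = tgt, peptide = pep, sequence = seq,
                 seed_window = enumerate_dipeptides(seq)[[1]],
                 rng_seed = rng_seed),
            class = "planted_complex")
}

#' @export
print.planted_complex <- function(x, ...) {
  cat(sprintf("<planted_complex> %s: receptor %d atoms, peptide %d residues (seed window %d:%s)\n",
              paste(x$sequence$residues, collapse = ""), nrow(x$target),
              length(x$sequence$residues), x$seed_window$start,
              x$seed_window$residues))
  invisible(x)
}

## Rotate all atoms "downstream" of a backbone bond; used for torsion
## perturbation.  `axis_from`/`axis_to` are positions; `move` is a logical
## row mask of atoms to rotate.
rotate_about_bond <- function(xyz, axis_from, axis_to, move, angle) {
  R <- axis_rotation(axis_to - axis_from, angle)
  xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2, axis_to) %*%
                         t(R), 2, axis_to, "+")
  xyz
}

## Apply Gaussian noise to every backbone phi/psi torsion of a peptide
## (atoms must be grouped by residue).  Returns the perturbed structure.
perturb_dihedrals <- function(s, sd_deg = 10) {
  xyz <- coords(s)
  resnos <- sort(unique(s$resno))
  for (r in resnos) {
    sel_r <- s$resno == r
    iN <- which(sel_r & s$name == "N")
    iCA <- which(sel_r & s$name == "CA")
    iC <- which(sel_r & s$name == "C")
    if (length(iN) == 0 || length(iCA) == 0 || length(iC) == 0) next
    ## phi: rotate everything past CA (side chain beyond CB stays rigid
    ## with the downstream mass)
    down_phi <- s$resno > r | (sel_r & !(s$name %in%
                                           c("N", "H1", "H2", "HN", "CA")))
    if (any(down_phi))
      xyz <- rotate_about_bond(xyz, xyz[iN, ], xyz[iCA, ], down_phi,
                               stats::rnorm(1, 0, sd_deg))
    ## psi: rotate everything past C
    down_psi <- s$resno > r | (sel_r & s$name %in% c("O", "OXT", "HXT"))
    if (any(down_psi))
      xyz <- rotate_about_bond(xyz, xyz[iCA, ], xyz[iC, ], down_psi,
                               stats::rnorm(1, 0, sd_deg))
  }
  set_coords(s, xyz)
}

#' Perturb a pose by a rigid displacement plus torsion noise
#'
#' Applies a random rigid-body displacement (rotation about a random axis
#' through the centroid plus a random translation) and Gaussian noise on
#' every backbone phi/psi torsion.  Both contributions scale with
#' `magnitude`, so the expected RMSD to the input grows monotonically with
#' it; `magnitude = 0` returns the input unchanged.
#'
#' @param s a `pepstruct`.
#' @param magnitude perturbation scale, Angstrom-like units: translation is
#'   uniform in a ball of this radius, rotation angle and torsion noise are
#'   `4 * magnitude` degrees (sd).
#' @param rng_seed integer seed.
#' @return the perturbed structure.
#' @export
perturb_pose <- function(s, magnitude, rng_seed = 1) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(s)
  set.seed(rng_seed)
  s <- perturb_dihedrals(s, sd_deg = 4 * magnitude)
  xyz <- coords(s)
  cen <- colMeans(xyz)
  ax <- stats::rnorm(3)
  R <- axis_rotation(ax, stats::rnorm(1, 0, 4 * magnitude))
  xyz <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen, "+")
  tr <- stats::rnorm(3)
  tr <- tr / sqrt(sum(tr^2)) * stats::runif(1, 0, magnitude)
  set_coords(s, sweep(xyz, 2, tr, "+"))
}
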