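## Intermolecular interaction energy: pairwise 12-6 Lennard-Jones plus
## Coulomb with the Mehler-Solmajer distance-dependent dielectric, summed
## over all ligand x target atom pairs and attributed to ligand residues.

## kcal*Angstrom/(mol*e^2); converts q_i*q_j/r to kcal/mol.
.coulomb_const <- 332.0637

#' Parameters of the sigmoidal distance-dependent dielectric
#'
#' The relative permittivity is modelled as
#' `eps_r(r) = A + B / (1 + k * exp(-lambda * B * r))` with
#' `B = eps0_water - A`, rising sigmoidally from a low value at contact
#' distances to the bulk-water dielectric constant at long range.  Defaults
#' are the original Mehler-Solmajer constants with water at 25 C.
#'
#' @param A dimensionless offset constant.
#' @param eps0_water bulk dielectric constant of water at 25 C.
#' @param k dimensionless steepness constant.
#' @param lam screening constant, 1/Angstrom.
#' @return object of class `dielectric_params` with the derived `B`.
#' @export
dielectric_params <- function(A = -8.5525, eps0_water = 78.4,
                              k = 7.7839, lam = 0.003627) {
  stopifnot(lam > 0, k > 0)
  structure(list(A = A, eps0_water = eps0_water, k = k, lam = lam,
                 B = eps0_water - A),
            class = "dielectric_params")
}

#' Distance-dependent relative permittivity
#'
#' @param r distance(s), Angstrom; must be non-negative.
#' @param p a [dielectric_params()] object.
#' @return eps_r at each distance; strictly increasing in `r`, bounded by
#'   `A + B/(1+k)` at r = 0 and `eps0_water` as r grows.
#' @export
dielectric <- function(r, p = dielectric_params()) {
  if (any(r < 0)) stop("negative distance in dielectric()")
  p$A + p$B / (1 + p$k * exp(-p$lam * p$B * r))
}

#' Lennard-Jones and Coulomb energy of one atom pair
#'
#' The 12-6 term uses `A_ij = eps_ij * R_ij^12`, `B_ij = 2 eps_ij R_ij^6`
#' with `R_ij = R_i + R_j` and `eps_ij = sqrt(eps_i * eps_j)`, so the
#' minimum sits at `r = R_ij` with depth `-eps_ij`.  The Coulomb term is
#' `C * q_i q_j / (eps_r(r) * r)` with C = 332.0637 kcal A / (mol e^2).
#'
#' @param a_i,a_j single-row `pepstruct` slices (or lists with `x`,`y`,`z`,
#'   `charge`, `radius`, `eps`).
#' @param p a [dielectric_params()] object.
#' @return named numeric: `E_LJ`, `E_Coulomb` (kcal/mol).
#' @export
pair_energy <- function(a_i, a_j, p = dielectric_params()) {
  if (is.na(a_i$radius) || is.na(a_j$radius) ||
      is.na(a_i$charge) || is.na(a_j$charge))
    stop("pair_energy: atoms are not parameterised")
  r <- sqrt((a_i$x - a_j$x)^2 + (a_i$y - a_j$y)^2 + (a_i$z - a_j$z)^2)
  if (r == 0) stop("pair_energy: overlapping atoms (r = 0)")
  Rij <- a_i$radius + a_j$radius
  eij <- sqrt(a_i$eps * a_j$eps)
  lj <- eij * (Rij / r)^12 - 2 * eij * (Rij / r)^6
  cou <- .coulomb_const * a_i$charge * a_j$charge / (dielectric(r, p) * r)
  c(E_LJ = lj, E_Coulomb = cou)
}

## Precomputed pair tables for repeated scoring of the same ligand/target
## composition at varying coordinates.
make_pair_context <- function(lig, tgt, p = dielectric_params()) {
  if (anyNA(lig$radius) || anyNA(tgt$radius) ||
      anyNA(lig$charge) || anyNA(tgt$charge))
    stop("make_pair_context: unparameterised atoms present")
  Rij <- outer(lig$radius, tgt$radius, "+")
  eij <- sqrt(outer(lig$eps, tgt$eps))
  list(A = eij * Rij^12,
       B = 2 * eij * Rij^6,
       QQ = .coulomb_const * outer(lig$charge, tgt$charge),
       tgt_xyz = coords(tgt),
       p = p)
}

## Pairwise squared distances between two coordinate matrices.
dist2_matrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}

## Fast path: total or per-ligand-atom LJ/Coulomb for given ligand coords.
context_energy <- function(ctx, lig_xyz, by_atom = FALSE) {
  r <- sqrt(dist2_matrix(lig_xyz, ctx$tgt_xyz))
  if (any(r == 0)) stop("overlapping ligand/target atoms (r = 0)")
  inv6 <- r^-6
  lj <- ctx$A * inv6 * inv6 - ctx$B * inv6
  p <- ctx$p
  eps_r <- p$A + p$B / (1 + p$k * exp(-p$lam * p$B * r))
  cou <- ctx$QQ / (eps_r * r)
  if (by_atom) list(lj = rowSums(lj), coulomb = rowSums(cou))
  else c(E_LJ = sum(lj), E_Coulomb = sum(cou))
}

#' Intermolecular interaction energy with per-residue decomposition
#'
#' Sums Lennard-Jones and Coulomb terms over all ligand-atom x target-atom
#' pairs (no exclusions; the two structures must be distinct molecules) and
#' attributes every pair to the ligand atom's residue.
#'
#' @param ligand,target parameterised `pepstruct` objects.
#' @param p a [dielectric_params()] object.
#' @param first_n report the energy summed over ligand residues
#'   `1..first_n` (by order of appearance) as `first_n_total`; default 5.
#' @return object of class `energy_report`: list with `per_residue`
#'   (data.frame: residue, resid, E_LJ, E_Coulomb, E_inter), `total`
#'   (named numeric E_LJ/E_Coulomb/E_inter) and `first_n_total`.
#' @export
interaction_energy <- function(ligand, target, p = dielectric_params(),
                               first_n = 5) {
  ctx <- make_pair_context(ligand, target, p)
  r <- sqrt(dist2_matrix(coords(ligand), ctx$tgt_xyz))
  if (any(r == 0)) stop("overlapping ligand/target atoms (r = 0)")
  inv6 <- r^-6
  lj <- rowSums(ctx$A * inv6 * inv6 - ctx$B * inv6)
  eps_r <- p$A + p$B / (1 + p$k * exp(-p$lam * p$B * r))
  cou <- rowSums(ctx$QQ / (eps_r * r))
  res <- residues(ligand)
  res_index <- match(paste(ligand$chain, ligand$resno),
                     paste(res$chain, res$resno))
  per <- data.frame(
    residue = seq_len(nrow(res)),
    resid = res$resid,
    E_LJ = as.numeric(rowsum(lj, res_index)),
    E_Coulomb = as.numeric(rowsum(cou, res_index)))
  per$E_inter <- per$E_LJ + per$E_Coulomb
  total <- c(E_LJ = sum(per$E_LJ), E_Coulomb = sum(per$E_Coulomb))
  total <- c(total, E_inter = unname(total[1] + total[2]))
  sel <- per$residue <= first_n
  structure(list(per_residue = per, total = total,
                 first_n = first_n,
                 first_n_total = sum(per$E_inter[sel])),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> E_inter %.3f kcal/mol (LJ %.3f, Coulomb %.3f); first %d residues: %.3f\n",
              x$total["E_inter"], x$total["E_LJ"], x$total["E_Coulomb"],
              x$first_n, x$first_n_total))
  invisible(x)
}

#' Per-residue interaction-energy profile over a set of complexes
#'
#' For each ligand residue position (1-based from the N-terminus), computes
#' the mean and standard deviation of per-residue `E_inter` over the
#' complexes whose ligand reaches that position; shorter peptides simply
#' contribute to fewer positions.
#'
#' @param complexes list of `list(ligand = , target = )` pairs, ligands
#'   sharing a common N-terminal numbering.
#' @param p a [dielectric_params()] object.
#' @return data.frame: residue, mean_E_inter, sd_E_inter, n.
#' @export
per_residue_profile <- function(complexes, p = dielectric_params()) {
  if (length(complexes) == 0) stop("per_residue_profile: empty input")
  vals <- lapply(complexes, function(cx) {
    rep <- interaction_energy(cx$ligand, cx$target, p)
    rep$per_residue[, c("residue", "E_inter")]
  })
  all_pos <- sort(unique(unlist(lapply(vals, `[[`, "residue"))))
  out <- do.call(rbind, lapply(all_pos, function(pos) {
    e <- unlist(lapply(vals, function(v) v$E_inter[v$residue == pos]))
    data.frame(residue = pos, mean_E_inter = mean(e),
               sd_E_inter = if (length(e) > 1) stats::sd(e) else 0,
               n = length(e))
  }))
  rownames(out) <- NULL
  out
}
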