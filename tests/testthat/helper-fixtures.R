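# Shared test helpers: small random parameterised structures and an
# independent brute-force energy oracle.

# Random parameterised structure: n atoms with plausible charges and the
# shipped vdW parameters, placed in a cube of the given edge, offset by
# `shift`.
random_structure <- function(n, edge = 10, shift = c(0, 0, 0),
                             chain = "X", n_residues = max(1, n %/% 4)) {
  elements <- sample(c("C", "N", "O", "S", "H"), n, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.05, 0.05))
  vdw <- seedgrow:::vdw_for_element(elements)
  df <- data.frame(
    serial = seq_len(n),
    name = paste0(elements, seq_len(n)),
    element = elements,
    resid = "ALA",
    chain = chain,
    resno = sort(sample.int(n_residues, n, replace = TRUE)),
    x = runif(n, 0, edge) + shift[1],
    y = runif(n, 0, edge) + shift[2],
    z = runif(n, 0, edge) + shift[3],
    charge = round(runif(n, -0.5, 0.5), 3),
    radius = vdw$radius,
    eps = vdw$eps,
    is_h = elements == "H",
    stringsAsFactors = FALSE)
  seedgrow:::new_pepstruct(df)
}

# Independent brute-force oracle for the pairwise intermolecular energy:
# an explicit double loop over scalar pair terms, written directly from the
# 12-6 + screened-Coulomb definition.
brute_force_energy <- function(ligand, target, p = dielectric_params()) {
  e_lj <- 0
  e_cou <- 0
  per_res <- numeric(max(ligand$resno))
  for (i in seq_len(nrow(ligand))) {
    for (j in seq_len(nrow(target))) {
      dx <- ligand$x[i] - target$x[j]
      dy <- ligand$y[i] - target$y[j]
      dz <- ligand$z[i] - target$z[j]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      Rij <- ligand$radius[i] + target$radius[j]
      eij <- sqrt(ligand$eps[i] * target$eps[j])
      lj <- eij * (Rij / r)^12 - 2 * eij * (Rij / r)^6
      eps_r <- p$A + (p$eps0_water - p$A) /
        (1 + p$k * exp(-p$lam * (p$eps0_water - p$A) * r))
      cou <- 332.0637 * ligand$charge[i] * target$charge[j] / (eps_r * r)
      e_lj <- e_lj + lj
      e_cou <- e_cou + cou
      per_res[ligand$resno[i]] <- per_res[ligand$resno[i]] + lj + cou
    }
  }
  list(E_LJ = e_lj, E_Coulomb = e_cou, E_inter = e_lj + e_cou,
       per_residue = per_res)
}

# Random rigid transform (rotation + translation) applied to a coordinate
# matrix.
random_rigid <- function() {
  ax <- rnorm(3)
  list(rotation = seedgrow:::axis_rotation(ax, runif(1, 0, 360)),
       translation = rnorm(3, 0, 20))
}

transform_structure <- function(s, tr) {
  xyz <- seedgrow:::coords(s)
  seedgrow:::set_coords(s, sweep(xyz %*% t(tr$rotation), 2,
                                 tr$translation, "+"))
}

# Light-weight configurations for smoke tests of the search stages.
light_dock_cfg <- function(rng_seed = 1)
  dock_config(n_runs = 2, orientations_per_run = 16, n_conformers = 2,
              keep_per_run = 3, refine_steps = 15, rng_seed = rng_seed)

light_growth_cfg <- function(rng_seed = 1, n_models = 10)
  growth_config(n_models = n_models, candidates_per_residue = 6,
                max_retries = 20, rng_seed = rng_seed)
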