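# Small synthetic pools: jittered copies of a parameterised dipeptide near
# a tiny receptor, cheap enough to score by the thousand.
make_tiny_system <- function() {
  lig <- assign_parameters(build_peptide(c("ALA", "SER")))
  tgt <- seedgrow:::new_pepstruct(data.frame(
    serial = 1:6, name = "CB", element = "C", resid = "ALA", chain = "T",
    resno = 1:6, x = seq(-2, 8, 2), y = -4.2, z = 0,
    charge = 0, radius = 2, eps = 0.15, is_h = FALSE))
  list(lig = lig, tgt = tgt)
}

jitter_pool <- function(lig, n, sd = 0.5, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    seedgrow:::set_coords(lig, seedgrow:::coords(lig) +
                            matrix(rnorm(3 * nrow(lig), 0, sd),
                                   ncol = 3)))
}

test_that("pool scoring ranks by the first-N energy and matches re-scoring", {
  sys <- make_tiny_system()
  pool <- jitter_pool(sys$lig, 25, seed = 4)
  rp <- score_pool(pool, sys$tgt, first_n = 1)
  expect_equal(nrow(rp$table), 25)
  expect_true(!is.unsorted(rp$table$E_inter_first))
  # scores equal an independent re-run of the energy engine per model
  for (k in c(1, 10, 25)) {
    id <- rp$table$model_id[k]
    e <- interaction_energy(pool[[id]], sys$tgt, first_n = 1)
    expect_equal(rp$table$E_inter_full[k], unname(e$total["E_inter"]),
                 tolerance = 1e-12)
    expect_equal(rp$table$E_inter_first[k], e$first_n_total,
                 tolerance = 1e-12)
  }
  # a pool of one: that model is rank 1 and the representative
  rp1 <- select_representative(score_pool(pool[1], sys$tgt))
  expect_equal(rp1$representative, 1)
  expect_equal(rp1$top_set, 1)
})

test_that("first-N ranking can disagree with full-ligand ranking on a C-terminal decoy", {
  # a strong contact site under residue 3 and a weak one under residue 1;
  # model B is the ligand shifted along its own chain axis so residue 1
  # occupies the strong site: B wins the first-residue score while A wins
  # the full-ligand score through its extra C-terminal contacts
  lig <- assign_parameters(build_peptide(c("ALA", "ALA", "ALA")))
  at <- function(r, nm) unlist(lig[lig$resno == r & lig$name == nm,
                                   c("x", "y", "z")])
  delta <- at(3, "CA") - at(1, "CA")
  u <- delta / sqrt(sum(delta^2))
  p <- seedgrow:::cross3(delta, at(1, "CB") - at(1, "CA"))
  p <- p / sqrt(sum(p^2))
  sites <- rbind(at(3, "CA") + 4.6 * p,
                 at(3, "CA") + 4.6 * p + 1.2 * u,
                 at(3, "CA") + 4.6 * p - 1.2 * u,
                 at(1, "CA") + 4.6 * p)
  tgt <- seedgrow:::new_pepstruct(data.frame(
    serial = 1:4, name = "CB", element = "C", resid = "ALA", chain = "T",
    resno = 1:4, x = sites[, 1], y = sites[, 2], z = sites[, 3],
    charge = 0, radius = 2, eps = 0.15, is_h = FALSE))
  a <- lig
  b <- seedgrow:::set_coords(lig, sweep(seedgrow:::coords(lig), 2, delta,
                                        "+"))
  rp <- score_pool(list(a, b), tgt, first_n = 1)
  full_order <- rp$table$model_id[order(rp$table$E_inter_full)]
  first_order <- rp$table$model_id[order(rp$table$E_inter_first)]
  expect_equal(first_order[1], 2)
  expect_equal(full_order[1], 1)
})

test_that("representative selection matches the brute-force RMSD-to-mean argmin", {
  sys <- make_tiny_system()
  pool <- jitter_pool(sys$lig, 200, sd = 1.0, seed = 9)
  rp <- select_representative(score_pool(pool, sys$tgt, top_fraction = 0.05))
  expect_length(rp$top_set, 10)         # ceil(0.05 * 200)
  # brute force: mean heavy coordinates over the top set, argmin member
  mats <- lapply(rp$top_set, function(id)
    seedgrow:::coords(seedgrow:::heavy(pool[[id]])))
  mean_xyz <- Reduce(`+`, mats) / length(mats)
  rms <- vapply(mats, function(m) sqrt(mean(rowSums((m - mean_xyz)^2))),
                numeric(1))
  expect_equal(rp$representative, rp$top_set[which.min(rms)])
  # representative is a member of the top set, never a synthetic average
  expect_true(rp$representative %in% rp$top_set)
  # permutation invariance (up to the documented lowest-id tie-break)
  perm <- sample(length(pool))
  rp2 <- select_representative(score_pool(pool[perm], sys$tgt,
                                          top_fraction = 0.05))
  expect_equal(sort(perm[rp2$top_set]), sort(rp$top_set))
  expect_equal(perm[rp2$representative], rp$representative)
})

test_that("identical top-set structures tie-break to the lowest model id", {
  sys <- make_tiny_system()
  pool <- rep(list(sys$lig), 7)
  rp <- select_representative(score_pool(pool, sys$tgt,
                                         top_fraction = 0.5))
  expect_equal(rp$representative, min(rp$top_set))
})

test_that("ablation rankings permute the same ids and E_inter reproduces the default", {
  sys <- make_tiny_system()
  pool <- jitter_pool(sys$lig, 30, seed = 12)
  rp <- score_pool(pool, sys$tgt)
  ids_e <- ranking_ablation(rp, "E_inter")
  ids_lj <- ranking_ablation(rp, "LJ_only")
  ids_q <- ranking_ablation(rp, "Coulomb_only")
  expect_equal(ids_e, rp$table$model_id)
  expect_setequal(ids_lj, ids_e)
  expect_setequal(ids_q, ids_e)
})

test_that("ranking separates an electrostatics-dominated planted pose", {
  # receptor with a charged oxygen: the combined score ranks the
  # charge-contacting model above the choice of the LJ-only ranking
  lig <- assign_parameters(build_peptide(c("LYS", "ALA")))
  tgt <- seedgrow:::new_pepstruct(data.frame(
    serial = 1:2, name = c("OG", "CB"), element = c("O", "C"),
    resid = c("SER", "ALA"), chain = "T", resno = 1:2,
    x = c(0, 30), y = c(-30, -3.8), z = 0,
    charge = NA_real_, radius = NA_real_, eps = NA_real_, is_h = FALSE))
  tgt <- assign_parameters(tgt)
  nz <- which(lig$name == "NZ")
  # model 1: lysine ammonium next to the charged oxygen
  shift1 <- c(0, -26, 0) - unlist(lig[nz, c("x", "y", "z")]) + c(0, -0.5, 0)
  m1 <- seedgrow:::set_coords(lig, sweep(seedgrow:::coords(lig), 2,
                                         -shift1))
  # model 2: backbone resting on the neutral carbon
  shift2 <- c(30, 0, 0) - unlist(lig[1, c("x", "y", "z")])
  m2 <- seedgrow:::set_coords(lig, sweep(seedgrow:::coords(lig), 2,
                                         -shift2))
  rp <- score_pool(list(m1, m2), tgt, first_n = 2)
  expect_equal(ranking_ablation(rp, "E_inter")[1], 1)
  expect_equal(ranking_ablation(rp, "LJ_only")[1], 2)
})
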