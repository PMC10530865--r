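test_that("target superposition recovers rigid transforms", {
  # a protein-like target (the built peptide, which has C-alpha atoms)
  # with a ligand rigidly attached to it
  tgt <- build_peptide(c("ALA", "ARG", "THR", "LYS", "GLN"), chain = "A")
  lig <- build_peptide(c("GLY", "SER"), chain = "P")
  lig <- seedgrow:::set_coords(lig, seedgrow:::coords(lig) +
                                 rep(c(0, 8, 0), each = nrow(lig)))
  ref <- list(target = tgt, ligand = lig)
  # identical targets: identity transform
  fit0 <- superpose_targets(ref, ref)
  expect_lt(max(abs(fit0$transform$rotation - diag(3))), 1e-8)
  expect_lt(max(abs(fit0$transform$translation)), 1e-8)
  # 90-degree rotation about z is inverted exactly
  Rz <- seedgrow:::axis_rotation(c(0, 0, 1), 90)
  rot <- list(target = transform_structure(tgt,
                                           list(rotation = Rz,
                                                translation = c(0, 0, 0))),
              ligand = transform_structure(lig,
                                           list(rotation = Rz,
                                                translation = c(0, 0, 0))))
  fit90 <- superpose_targets(rot, ref)
  expect_equal(fit90$transform$rotation %*% Rz, diag(3), tolerance = 1e-6)
  # random rigid transform: post-superposition target CA RMSD < 1e-6 and
  # the ligand returns to the reference frame with it
  set.seed(5)
  tr <- random_rigid()
  model <- list(target = transform_structure(tgt, tr),
                ligand = transform_structure(lig, tr))
  out <- superpose_targets(model, ref)
  expect_lt(out$transform$rmsd, 1e-6)
  expect_lt(ligand_rmsd(out$complex$ligand, lig), 1e-6)
})

test_that("ligand RMSD matches the closed forms and an independent oracle", {
  pep <- build_peptide(c("ALA", "ARG", "THR", "LYS", "GLN", "THR"))
  expect_equal(ligand_rmsd(pep, pep), 0)
  # one heavy atom displaced by d: RMSD = d / sqrt(N)
  n_heavy <- sum(!pep$is_h)
  moved <- pep
  i <- which(!moved$is_h)[7]
  moved$x[i] <- moved$x[i] + 2.4
  expect_equal(ligand_rmsd(moved, pep), 2.4 / sqrt(n_heavy),
               tolerance = 1e-12)
  # random displacement: direct formula and bio3d agree
  set.seed(6)
  rnd <- seedgrow:::set_coords(pep, seedgrow:::coords(pep) +
                                 matrix(rnorm(3 * nrow(pep), 0, 1),
                                        ncol = 3))
  mine <- ligand_rmsd(rnd, pep)
  hx <- !pep$is_h
  expect_equal(mine, sqrt(mean(rowSums(
    (seedgrow:::coords(rnd)[hx, ] - seedgrow:::coords(pep)[hx, ])^2))),
    tolerance = 1e-10)
  b3d <- bio3d::rmsd(as.numeric(t(seedgrow:::coords(pep)[hx, ])),
                     as.numeric(t(seedgrow:::coords(rnd)[hx, ])))
  expect_equal(mine, b3d, tolerance = 1e-3)
  # invariance under a joint rigid transformation of both structures
  tr <- random_rigid()
  expect_equal(ligand_rmsd(transform_structure(rnd, tr),
                           transform_structure(pep, tr)), mine,
               tolerance = 1e-8)
  # first-N subset uses exactly the heavy atoms of residues 1..N
  sub <- ligand_rmsd(rnd, pep, "first_n", first_n = 2)
  hx2 <- !pep$is_h & pep$resno <= 2
  expect_equal(sub, sqrt(mean(rowSums(
    (seedgrow:::coords(rnd)[hx2, ] - seedgrow:::coords(pep)[hx2, ])^2))),
    tolerance = 1e-10)
  # mismatched composition errors with the offending atoms listed
  drop_heavy <- which(!pep$is_h)[3]
  expect_error(ligand_rmsd(pep[-drop_heavy, ], pep), "mismatch")
})

test_that("benchmark statistics compute RMSD_best/RMSD_top per system", {
  systems <- list(
    s1 = data.frame(rmsd_full = c(5, 3, 8), rmsd_first = c(4, 2, 6),
                    score = c(-10, -5, -20)),
    s2 = data.frame(rmsd_full = 4, rmsd_first = 3, score = -7),
    s3 = data.frame(rmsd_full = c(6, 2), rmsd_first = c(5, 1),
                    score = c(-30, -1)))
  st <- benchmark_stats(systems)
  # hand-computed table
  expect_equal(st$per_system$rmsd_best_full, c(3, 4, 2))
  expect_equal(st$per_system$rmsd_top_full, c(8, 4, 6))
  expect_equal(st$per_system$rmsd_best_first, c(2, 3, 1))
  expect_equal(st$per_system$rmsd_top_first, c(6, 3, 5))
  # single-mode system: best equals top by necessity
  expect_equal(st$per_system$rmsd_best_full[2],
               st$per_system$rmsd_top_full[2])
  # summary means/sds match a spreadsheet-style hand computation
  expect_equal(st$summary$mean[st$summary$metric == "rmsd_best_full"],
               mean(c(3, 4, 2)))
  expect_equal(st$summary$sd[st$summary$metric == "rmsd_top_first"],
               stats::sd(c(6, 3, 5)))
  # RMSD_top >= RMSD_best always
  expect_true(all(st$per_system$rmsd_top_full >=
                    st$per_system$rmsd_best_full))
  # perfect scoring makes the means coincide
  perfect <- list(a = data.frame(rmsd_full = c(2, 5), rmsd_first = c(1, 4),
                                 score = c(-9, -1)))
  stp <- benchmark_stats(perfect)
  expect_equal(stp$per_system$rmsd_top_full, stp$per_system$rmsd_best_full)
  # empty systems are excluded with a warning
  expect_warning(benchmark_stats(c(systems,
                                   list(empty = data.frame()))),
                 "empty")
})
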