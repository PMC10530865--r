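make_seed_pose <- function(px, offset = 0) {
  # the planted window itself, with caps rebuilt, as an idealised seed pose
  frag <- build_fragment(px$seed_window)
  ref <- px$peptide[px$peptide$resno <= 2, ]
  key_f <- paste(frag$resno, frag$name)
  key_r <- paste(ref$resno, ref$name)
  common <- intersect(key_f, key_r)
  fit <- seedgrow:::kabsch_fit(
    seedgrow:::coords(frag)[match(common, key_f), , drop = FALSE],
    seedgrow:::coords(ref)[match(common, key_r), , drop = FALSE])
  placed <- seedgrow:::set_coords(
    frag, seedgrow:::apply_transform(seedgrow:::coords(frag), fit) + offset)
  seedgrow:::new_pose(placed, 0)
}

test_that("grown models satisfy the geometric contracts", {
  px <- make_planted_complex(6, rng_seed = 42)
  seed <- make_seed_pose(px)
  cfg <- growth_config(n_models = 20, rng_seed = 3)
  models <- grow_peptide(px$target, seed, px$sequence, px$seed_window, cfg)
  expect_gt(length(models), 0)
  tgt_h <- seedgrow:::heavy(px$target)
  for (m in models) {
    # full sequence length, canonical residue numbering
    expect_equal(sort(unique(m$resno)), 1:6)
    expect_equal(unique(m$resid[m$resno == 2]), "ARG")
    # peptide bond lengths within 1.33 +- 0.05 A
    for (r in 1:5) {
      ci <- which(m$resno == r & m$name == "C")
      ni <- which(m$resno == r + 1 & m$name == "N")
      d <- sqrt(sum((seedgrow:::coords(m)[ci, ] -
                       seedgrow:::coords(m)[ni, ])^2))
      expect_equal(d, 1.33, tolerance = 0.05 / 1.33)
    }
    # seed backbone anchored within 0.3 A
    for (r in 1:2) for (nm in c("N", "CA", "C", "O")) {
      mi <- which(m$resno == r & m$name == nm)
      si <- which(seed$structure$resno == r & seed$structure$name == nm)
      expect_lt(sqrt(sum((seedgrow:::coords(m)[mi, ] -
                            seedgrow:::coords(seed$structure)[si, ])^2)),
                0.3)
    }
    # no ligand-target heavy-atom pair closer than 0.7 * (R_i + R_j)
    mh <- seedgrow:::heavy(m)
    dm <- sqrt(seedgrow:::dist2_matrix(seedgrow:::coords(mh),
                                       seedgrow:::coords(tgt_h)))
    lim <- 0.7 * outer(mh$radius, tgt_h$radius, "+")
    expect_true(all(dm >= lim))
    # L-configuration at every C-alpha
    for (r in unique(m$resno)) {
      nm_r <- m[m$resno == r, ]
      if (!"CB" %in% nm_r$name) next
      g <- function(nm) unlist(nm_r[nm_r$name == nm, c("x", "y", "z")])
      expect_gt(det(rbind(g("N") - g("CA"), g("C") - g("CA"),
                          g("CB") - g("CA"))), 0)
    }
    # fully parameterised
    expect_false(anyNA(m$charge))
  }
  # determinism
  models2 <- grow_peptide(px$target, seed, px$sequence, px$seed_window, cfg)
  expect_equal(lapply(models, seedgrow:::coords),
               lapply(models2, seedgrow:::coords))
})

test_that("an internal seed grows in both directions", {
  px <- make_planted_complex(6, rng_seed = 8)
  # seed window 2:RT, acetyl-capped: requires one N-ward residue
  spec <- enumerate_dipeptides(px$sequence)[[2]]
  frag <- build_fragment(spec)
  ref <- px$peptide[px$peptide$resno %in% c(2, 3), ]
  key_f <- paste(frag$resno, frag$name)
  key_r <- paste(ref$resno, ref$name)
  common <- intersect(key_f, key_r)
  fit <- seedgrow:::kabsch_fit(
    seedgrow:::coords(frag)[match(common, key_f), , drop = FALSE],
    seedgrow:::coords(ref)[match(common, key_r), , drop = FALSE])
  pose <- seedgrow:::new_pose(seedgrow:::set_coords(
    frag, seedgrow:::apply_transform(seedgrow:::coords(frag), fit)), 0)
  models <- grow_peptide(px$target, pose, px$sequence, spec,
                         light_growth_cfg(n_models = 5))
  for (m in models) {
    expect_equal(sort(unique(m$resno)), 1:6)
    # N-terminal amine present on residue 1, carboxylate on residue 6
    expect_true(all(c("H1", "H2") %in% m$name[m$resno == 1]))
    expect_true("OXT" %in% m$name[m$resno == 6])
    # junction bond between grown residue 1 and seed residue 2
    d <- sqrt(sum((unlist(m[m$resno == 1 & m$name == "C", c("x", "y", "z")]) -
                     unlist(m[m$resno == 2 & m$name == "N",
                              c("x", "y", "z")]))^2))
    expect_equal(d, 1.33, tolerance = 0.05 / 1.33)
  }
})

test_that("n_models = 1 yields exactly one model and pools tag seed ranks", {
  px <- make_planted_complex(6, rng_seed = 11)
  seed <- make_seed_pose(px)
  one <- grow_peptide(px$target, seed, px$sequence, px$seed_window,
                      growth_config(n_models = 1, rng_seed = 2))
  expect_length(one, 1)
  # a second, slightly perturbed seed pose standing in for rank 2
  seed2 <- seedgrow:::new_pose(perturb_pose(seed$structure, 0.3,
                                            rng_seed = 44), 0)
  seed$cluster_rank <- 1L
  seed2$cluster_rank <- 2L
  pool <- grow_from_all_ranks(px$target, list(seed, seed2), px$sequence,
                              px$seed_window, light_growth_cfg(n_models = 4))
  expect_lte(length(pool), 8)
  expect_setequal(unique(vapply(pool, `[[`, numeric(1), "seed_rank")),
                  c(1, 2))
  expect_equal(vapply(pool, `[[`, integer(1), "model_id"),
               seq_along(pool))
})

test_that("pool energies are robust to the growing seed at the distribution level", {
  px <- make_planted_complex(6, rng_seed = 42)
  seed <- make_seed_pose(px)
  med <- vapply(c(101, 202), function(s) {
    models <- grow_peptide(px$target, seed, px$sequence, px$seed_window,
                           growth_config(n_models = 30, rng_seed = s))
    stats::median(vapply(models, function(m)
      unname(interaction_energy(m, px$target)$total["E_inter"]),
      numeric(1)))
  }, numeric(1))
  expect_lt(abs(med[1] - med[2]) / abs(med[1]), 0.10)
})
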