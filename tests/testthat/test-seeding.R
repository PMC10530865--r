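test_that("search box geometry is consistent", {
  box <- search_box(c(1, 2, 3))
  expect_equal(box$extent, rep(59 * 0.375, 3))
  box2 <- search_box(c(0, 0, 0), n_points = c(21, 31, 41), spacing = 0.5)
  expect_equal(box2$extent, c(10, 15, 20))
})

test_that("seed docking recovers a planted pose and is deterministic", {
  px <- make_planted_complex(6, rng_seed = 42)
  frag <- build_fragment(px$seed_window)
  box <- search_box(colMeans(seedgrow:::coords(px$peptide)),
                    n_points = 50)
  cfg <- dock_config(n_runs = 5, rng_seed = 7)
  poses <- dock_seed(frag, px$target, box, cfg)
  expect_gt(length(poses), 0)
  rms <- vapply(poses, function(p)
    seedgrow:::seed_pose_rmsd(p$structure, px$peptide, px$seed_window),
    numeric(1))
  expect_lte(min(rms), 2.0)            # planted-truth recovery
  # scores sorted ascending, all finite
  sc <- vapply(poses, `[[`, numeric(1), "score")
  expect_true(all(is.finite(sc)))
  expect_true(!is.unsorted(sc))
  # all pose atoms inside the box
  for (p in poses)
    expect_true(seedgrow:::in_box(seedgrow:::coords(p$structure), box,
                                  margin = 1e-9))
  # determinism under the same seed
  poses2 <- dock_seed(frag, px$target, box, cfg)
  expect_equal(lapply(poses, function(p) seedgrow:::coords(p$structure)),
               lapply(poses2, function(p) seedgrow:::coords(p$structure)))
  # results shift exactly with a joint translation of target and box
  shift <- c(11, -7, 3)
  tgt_t <- seedgrow:::set_coords(px$target,
                                 seedgrow:::coords(px$target) +
                                   rep(shift, each = nrow(px$target)))
  box_t <- search_box(box$center + shift, n_points = 50)
  poses_t <- dock_seed(frag, tgt_t, box_t, cfg)
  for (k in seq_along(poses)) {
    moved <- seedgrow:::coords(poses_t[[k]]$structure)
    orig <- seedgrow:::coords(poses[[k]]$structure)
    expect_lt(sqrt(mean(rowSums((moved - rep(shift, each = nrow(orig)) -
                                   orig)^2))), 1e-6)
  }
})

test_that("a box far away from the target yields no poses, with a warning", {
  px <- make_planted_complex(6, rng_seed = 1)
  frag <- build_fragment(px$seed_window)
  box <- search_box(colMeans(seedgrow:::coords(px$target)) + 100,
                    n_points = 20)
  expect_warning(poses <- dock_seed(frag, px$target, box,
                                    light_dock_cfg()),
                 "surface")
  expect_length(poses, 0)
})

test_that("pose import round-trips coordinates and scores consistently", {
  px <- make_planted_complex(6, rng_seed = 3)
  frag <- build_fragment(px$seed_window)
  moved <- seedgrow:::set_coords(frag, seedgrow:::coords(frag) + 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(moved, path)
  imp <- import_poses(path, frag, px$target)
  expect_length(imp, 1)
  expect_equal(imp[[1]]$source, "imported")
  expect_equal(seedgrow:::coords(imp[[1]]$structure),
               seedgrow:::coords(moved), tolerance = 2e-3)
  # imported score equals an independent energy evaluation
  e <- interaction_energy(seedgrow:::set_coords(
    frag, seedgrow:::coords(imp[[1]]$structure)), px$target)
  expect_equal(imp[[1]]$score, unname(e$total["E_inter"]),
               tolerance = 1e-9)
  # missing atom is an error
  broken <- moved[-3, ]
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(broken, path2)
  expect_error(import_poses(path2, frag, px$target), "match")
})

test_that("leader clustering matches an independent all-pairs oracle", {
  set.seed(21)
  base <- assign_parameters(build_peptide(c("ALA", "ALA")))
  mk_pose <- function(center, score) {
    s <- seedgrow:::set_coords(base, sweep(seedgrow:::coords(base), 2,
                                           center, "+"))
    seedgrow:::new_pose(s, score)
  }
  # 50 random poses drawn around 4 well-separated centres
  centres <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 14, 0), c(9, 9, 9))
  poses <- lapply(1:50, function(i) {
    mk_pose(centres[sample.int(4, 1), ] + rnorm(3, 0, 0.3), rnorm(1))
  })
  reps <- cluster_and_rank(poses, tol = 2)
  # independent oracle: same greedy rule written against the full RMSD
  # matrix
  n <- length(poses)
  xyz <- lapply(poses, function(p)
    seedgrow:::coords(seedgrow:::heavy(p$structure)))
  rmat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    rmat[i, j] <- sqrt(mean(rowSums((xyz[[i]] - xyz[[j]])^2)))
  ord <- order(vapply(poses, `[[`, numeric(1), "score"))
  leader_idx <- integer(0)
  assign_to <- integer(n)
  for (i in ord) {
    hit <- which(rmat[i, leader_idx] <= 2)[1]
    if (is.na(hit)) {
      leader_idx <- c(leader_idx, i)
      assign_to[i] <- length(leader_idx)
    } else assign_to[i] <- hit
  }
  expect_length(reps, length(leader_idx))
  expect_equal(vapply(reps, `[[`, numeric(1), "score"),
               vapply(poses[leader_idx], `[[`, numeric(1), "score"))
  # representative scores non-decreasing with rank; every pose assigned
  expect_true(!is.unsorted(vapply(reps, `[[`, numeric(1), "score")))
  expect_equal(sum(vapply(reps, attr, integer(1), "cluster_size")), n)
  # identical poses collapse to one cluster
  same <- lapply(1:10, function(i) mk_pose(c(0, 0, 0), i))
  expect_length(cluster_and_rank(same, tol = 2), 1)
  # two groups 10+ A apart give two ranks ordered by score
  two <- c(lapply(1:5, function(i) mk_pose(c(0, 0, 0), i)),
           lapply(1:5, function(i) mk_pose(c(10, 0, 0), i - 10)))
  reps2 <- cluster_and_rank(two, tol = 2)
  expect_length(reps2, 2)
  expect_lt(reps2[[1]]$score, reps2[[2]]$score)
})
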