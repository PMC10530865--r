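## Seed docking: systematic rigid-body placement of the dipeptide fragment
## over a translational grid x orientation set inside a search box, scored
## with the intermolecular interaction energy, with rigid-body coordinate
## descent refinement of the best placements and greedy leader clustering
## of the resulting poses.

#' Define a rectangular search box
#'
#' @param center 3-vector, box centre in Angstrom.
#' @param n_points grid points per axis (scalar or 3-vector).
#' @param spacing grid spacing, Angstrom.
#' @return object of class `search_box`.
#' @export
search_box <- function(center, n_points = 60, spacing = 0.375) {
  n_points <- rep_len(as.integer(n_points), 3)
  stopifnot(all(n_points > 1), spacing > 0, length(center) == 3)
  structure(list(center = as.numeric(center), n_points = n_points,
                 spacing = spacing,
                 extent = (n_points - 1) * spacing),
            class = "search_box")
}

#' Seed docking configuration
#'
#' Desk-scale defaults for the systematic search: 10 independent search
#' replicates, each with its own random orientation/conformer draws; the
#' translational scan uses every `trans_stride`-th grid point.
#'
#' @param n_runs independent search replicates.
#' @param orientations_per_run random rigid orientations sampled per run.
#' @param n_conformers fragment conformers per run (the input conformation
#'   plus torsion-perturbed copies).
#' @param trans_stride translational scan stride in grid points.
#' @param keep_per_run best placements kept and refined per run.
#' @param refine_steps coordinate-descent iterations per kept placement.
#' @param surface_range centroid distance band (Angstrom) to the nearest
#'   target heavy atom for scanned grid points.
#' @param rng_seed seed for all random draws.
#' @return list of class `dock_config`.
#' @export
dock_config <- function(n_runs = 10, orientations_per_run = 58,
                        n_conformers = 3, trans_stride = 6,
                        keep_per_run = 6, refine_steps = 40,
                        surface_range = c(2.5, 7.0), rng_seed = 1) {
  structure(list(n_runs = n_runs,
                 orientations_per_run = orientations_per_run,
                 n_conformers = n_conformers, trans_stride = trans_stride,
                 keep_per_run = keep_per_run, refine_steps = refine_steps,
                 surface_range = surface_range, rng_seed = rng_seed),
            class = "dock_config")
}

new_pose <- function(structure, score, source = "internal") {
  structure(list(structure = structure, score = score,
                 cluster_rank = NA_integer_, source = source),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> score %.3f kcal/mol, rank %s, source %s\n",
              x$score,
              if (is.na(x$cluster_rank)) "-" else x$cluster_rank, x$source))
  invisible(x)
}

in_box <- function(xyz, box, margin = 0) {
  half <- box$extent / 2 + margin
  all(abs(sweep(xyz, 2, box$center)) <= rep(half, each = nrow(xyz)))
}

#' Dock a fragment into a search box on a rigid target
#'
#' Places torsion-perturbed conformers of the fragment by systematic
#' translation over a coarse grid restricted to the box (and to a band
#' around the target surface) combined with random rigid orientations,
#' scores every placement with the intermolecular interaction energy, and
#' refines the best placements per run by rigid-body coordinate descent.
#' Deterministic for a fixed `cfg$rng_seed`.
#'
#' @param fragment parameterised `pepstruct` of the capped dipeptide.
#' @param target parameterised `pepstruct` of the rigid receptor.
#' @param box a [search_box()].
#' @param cfg a [dock_config()].
#' @param p a [dielectric_params()] object.
#' @return list of `pose` objects (unclustered), sorted by score; empty
#'   with a warning when no placement survives.
#' @export
dock_seed <- function(fragment, target, box, cfg = dock_config(),
                      p = dielectric_params()) {
  set.seed(cfg$rng_seed)
  ctx <- make_pair_context(fragment, target, p)
  txyz_h <- coords(heavy(target))

  ## translational grid, restricted to a band around the target surface
  axes <- lapply(1:3, function(a) {
    half <- box$extent[a] / 2
    box$center[a] + seq(-half, half, by = box$spacing * cfg$trans_stride)
  })
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  dmin <- sqrt(apply(dist2_matrix(pts, txyz_h), 1, min))
  keep <- dmin >= cfg$surface_range[1] & dmin <= cfg$surface_range[2]
  if (!any(keep)) {
    warning("search box does not reach the target surface; no poses")
    return(list())
  }
  pts <- pts[keep, , drop = FALSE]

  fxyz0 <- coords(fragment)
  cen0 <- colMeans(fxyz0)
  fxyz0 <- sweep(fxyz0, 2, cen0)

  score_xyz <- function(xyz) unname(sum(context_energy(ctx, xyz)))

  ## flattened pair tables for the vectorised translational scan
  nl <- nrow(fxyz0)
  nt <- nrow(ctx$tgt_xyz)
  Avec <- as.vector(ctx$A)
  Bvec <- as.vector(ctx$B)
  QQvec <- as.vector(ctx$QQ)
  qnz <- which(QQvec != 0)   # Coulomb only needs charged pairs
  tgt_rep <- ctx$tgt_xyz[rep(seq_len(nt), each = nl), , drop = FALSE]
  lig_idx <- rep(seq_len(nl), nt)
  p2 <- rowSums(pts^2)
  tp <- t(pts)
  ## soft-core floor: the coarse scan clamps pair distances at 0.75 R_ij so
  ## that placements one grid step away from a good pose are not discarded
  ## for a transient overlap; refinement then uses the true potential
  soft_vec <- as.vector((0.75 * outer(fragment$radius,
                                      target$radius, "+"))^2)

  ## scan-level energy at every grid translation of one oriented conformer
  scan_positions <- function(rx) {
    Bm <- rx[lig_idx, , drop = FALSE] - tgt_rep
    d2 <- outer(rowSums(Bm^2), p2, "+") + 2 * (Bm %*% tp)
    d2 <- pmax(d2, soft_vec)
    inv2 <- 1 / d2
    inv6 <- inv2 * inv2 * inv2
    e <- colSums(Avec * inv6 * inv6 - Bvec * inv6)
    if (length(qnz) > 0) {
      rq <- sqrt(d2[qnz, , drop = FALSE])
      eps_r <- p$A + p$B / (1 + p$k * exp(-p$lam * p$B * rq))
      e <- e + colSums(QQvec[qnz] / (eps_r * rq))
    }
    e
  }

  poses <- list()
  for (run in seq_len(cfg$n_runs)) {
    ## conformers: input + torsion-perturbed copies (backbone pivots)
    confs <- list(fxyz0)
    if (cfg$n_conformers > 1) {
      for (k in seq_len(cfg$n_conformers - 1)) {
        s2 <- perturb_dihedrals(set_coords(fragment, fxyz0), sd_deg = 30)
        cc <- coords(s2)
        confs[[k + 1]] <- sweep(cc, 2, colMeans(cc))
      }
    }
    rots <- random_rotations(cfg$orientations_per_run)
    best <- list()
    for (ci in seq_along(confs)) {
      for (ri in seq_along(rots)) {
        rx <- confs[[ci]] %*% t(rots[[ri]])
        sc <- scan_positions(rx)
        pi <- which.min(sc)
        best[[length(best) + 1]] <-
          list(xyz = sweep(rx, 2, pts[pi, ], "+"), score = sc[pi])
      }
    }
    ord <- order(vapply(best, `[[`, numeric(1), "score"))
    for (b in best[ord[seq_len(min(cfg$keep_per_run, length(best)))]]) {
      ref <- refine_rigid(b$xyz, score_xyz, steps = cfg$refine_steps)
      if (!in_box(ref$xyz, box, margin = 1e-9)) next
      poses[[length(poses) + 1]] <-
        new_pose(set_coords(fragment, ref$xyz), ref$score)
    }
  }
  if (length(poses) == 0)
    warning("no clash-free pose found inside the box")
  poses[order(vapply(poses, `[[`, numeric(1), "score"))]
}

## Rigid-body coordinate descent: alternating +-translations along axes and
## +-rotations about axes through the centroid, with a shrinking step.
refine_rigid <- function(xyz, score_fn, steps = 40,
                         t_step = 1.2, r_step = 25) {
  sc <- score_fn(xyz)
  for (it in seq_len(steps)) {
    improved <- FALSE
    for (a in 1:3) {
      for (sgn in c(-1, 1)) {
        cand <- xyz; cand[, a] <- cand[, a] + sgn * t_step
        s2 <- score_fn(cand)
        if (s2 < sc) { xyz <- cand; sc <- s2; improved <- TRUE }
      }
    }
    cen <- colMeans(xyz)
    for (a in 1:3) {
      ax <- c(0, 0, 0); ax[a] <- 1
      for (sgn in c(-1, 1)) {
        R <- axis_rotation(ax, sgn * r_step)
        cand <- sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen, "+")
        s2 <- score_fn(cand)
        if (s2 < sc) { xyz <- cand; sc <- s2; improved <- TRUE }
      }
    }
    if (!improved) {
      t_step <- t_step / 2
      r_step <- r_step / 2
      if (t_step < 0.05) break
    }
  }
  list(xyz = xyz, score = sc)
}

#' Import externally produced fragment poses
#'
#' Reads docked poses (PDB or mol2) produced by an external docking tool,
#' checks that their atom composition matches the fragment template, and
#' scores them with the package's interaction energy so that imported and
#' internal poses rank on the same scale.
#'
#' @param paths character vector of pose files.
#' @param fragment_template parameterised `pepstruct` the poses must match
#'   (same atom names).
#' @param target parameterised receptor used for scoring.
#' @param p a [dielectric_params()] object.
#' @return list of `pose` objects with `source = "imported"`.
#' @export
import_poses <- function(paths, fragment_template, target,
                         p = dielectric_params()) {
  ctx <- make_pair_context(fragment_template, target, p)
  lapply(paths, function(path) {
    s <- read_structure(path)
    if (nrow(s) != nrow(fragment_template) ||
        !all(sort(s$name) == sort(fragment_template$name))) {
      missing <- setdiff(fragment_template$name, s$name)
      extra <- setdiff(s$name, fragment_template$name)
      stop("pose '", path, "' does not match the fragment template",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ",")),
           if (length(extra)) paste0("; unexpected: ",
                                     paste(extra, collapse = ",")))
    }
    ## align atom order to the template
    key_t <- paste(fragment_template$resno, fragment_template$name)
    key_s <- paste(s$resno, s$name)
    idx <- match(key_t, key_s)
    if (anyNA(idx)) idx <- match(fragment_template$name, s$name)
    s <- s[idx, , drop = FALSE]
    out <- set_coords(fragment_template, coords(s))
    new_pose(out, sum(context_energy(ctx, coords(out))),
             source = "imported")
  })
}

## Heavy-atom RMSD between two poses in the common target frame (no
## superposition).
pose_rmsd <- function(a, b) {
  ha <- !a$structure$is_h
  sqrt(mean(rowSums((coords(a$structure)[ha, , drop = FALSE] -
                     coords(b$structure)[ha, , drop = FALSE])^2)))
}

#' Cluster poses and pick one representative per rank
#'
#' Greedy leader clustering: poses are visited in order of increasing
#' score; each pose joins the first existing cluster whose leader lies
#' within `tol` heavy-atom RMSD (computed in the shared target frame,
#' without superposition), otherwise it founds a new cluster.  Clusters are
#' ranked by their best member's score; the representative of a rank is its
#' best-scoring member (the leader).
#'
#' @param poses list of `pose` objects.
#' @param tol clustering RMSD tolerance, Angstrom (default 2.0).
#' @return list of representative `pose` objects with `cluster_rank` set
#'   (1 = best), each carrying the attribute `cluster_size`.
#' @export
cluster_and_rank <- function(poses, tol = 2.0) {
  stopifnot(length(poses) >= 1)
  ord <- order(vapply(poses, `[[`, numeric(1), "score"))
  leaders <- list()
  sizes <- integer(0)
  for (i in ord) {
    pose <- poses[[i]]
    joined <- FALSE
    for (k in seq_along(leaders)) {
      if (pose_rmsd(pose, leaders[[k]]) <= tol) {
        sizes[k] <- sizes[k] + 1L
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      leaders[[length(leaders) + 1]] <- pose
      sizes[length(leaders)] <- 1L
    }
  }
  lapply(seq_along(leaders), function(k) {
    rep <- leaders[[k]]
    rep$cluster_rank <- k
    attr(rep, "cluster_size") <- sizes[k]
    rep
  })
}
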