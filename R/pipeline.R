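## End-to-end pipeline: fragment build -> seed dock (or import) ->
## cluster/rank -> grow from all ranks -> score pool -> representative
## selection -> optional RMSD evaluation against a reference pose.

#' Run the full seed-and-grow pipeline
#'
#' Orchestrates all stages on one target/peptide system.  The search box
#' defaults to the protocol grid (60 x 60 x 60 points at 0.375 Angstrom)
#' centred on the reference ligand centroid when a reference is given;
#' otherwise `box` (or at least `box_center`) must be supplied — blind
#' binding-site detection is deliberately not attempted.
#'
#' @param target parameterised receptor `pepstruct` (see
#'   [prepare_target()]), or a path to a PDB file to be prepared.
#' @param sequence a [peptide_sequence()] (or string) of the full peptide.
#' @param seed_spec a `fragment_spec` choosing the seed window; default
#'   window 1 (the N-terminal dipeptide).
#' @param box a [search_box()]; default built from the reference centroid.
#' @param box_center centre for the default box when no reference exists.
#' @param reference optional reference ligand `pepstruct` (experimental
#'   pose in the same target frame) for RMSD evaluation.
#' @param imported_poses optional list of externally docked seed `pose`s;
#'   when given, the internal seed docking stage is skipped.
#' @param dock_cfg,growth_cfg,dielec stage configurations
#'   ([dock_config()], [growth_config()], [dielectric_params()]).
#' @param max_ranks number of top seed ranks grown (default 5).
#' @param cluster_tol seed pose clustering tolerance, Angstrom.
#' @param top_fraction,first_n pool selection parameters (top 1% of models
#'   ranked by the interaction energy of the first `first_n` residues).
#' @param rng_seed master seed; stage seeds derive from it.
#' @param output_dir optional directory; when given, the solution PDB,
#'   ranking table, per-residue energy table, RMSD report and a run
#'   manifest are written there.
#' @param verbose log stage progress.
#' @return object of class `seedgrow_run`.
#' @export
run_pipeline <- function(target, sequence, seed_spec = NULL,
                         box = NULL, box_center = NULL, reference = NULL,
                         imported_poses = NULL,
                         dock_cfg = dock_config(),
                         growth_cfg = growth_config(),
                         dielec = dielectric_params(),
                         max_ranks = 5, cluster_tol = 2.0,
                         top_fraction = 0.01, first_n = 5,
                         rng_seed = 1, output_dir = NULL,
                         verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(target)) {
    if (!file.exists(target)) stop("target file not found: ", target)
    target <- prepare_target(read_structure(target))
  }
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  if (is.null(seed_spec)) seed_spec <- enumerate_dipeptides(sequence)[[1]]
  if (is.null(box)) {
    center <- if (!is.null(reference)) colMeans(coords(reference))
              else box_center
    if (is.null(center))
      stop("no search box: supply `box`, `box_center` or a `reference`")
    box <- search_box(center)
  }
  dock_cfg$rng_seed <- rng_seed
  growth_cfg$rng_seed <- rng_seed

  say("stage fragment: window %d:%s", seed_spec$start, seed_spec$residues)
  frag <- build_fragment(seed_spec)

  if (is.null(imported_poses)) {
    say("stage dock: %d runs x %d orientations", dock_cfg$n_runs,
        dock_cfg$orientations_per_run)
    poses <- dock_seed(frag, target, box, dock_cfg, dielec)
  } else {
    say("stage dock: using %d imported poses", length(imported_poses))
    poses <- imported_poses
  }
  if (length(poses) == 0) stop("seed docking produced no poses")
  say("stage dock: %d poses, best score %.2f", length(poses),
      poses[[1]]$score)

  reps <- cluster_and_rank(poses, tol = cluster_tol)
  reps <- reps[seq_len(min(max_ranks, length(reps)))]
  say("stage cluster: %d rank(s) used", length(reps))

  pool <- grow_from_all_ranks(target, reps, sequence, seed_spec,
                              growth_cfg, dielec)
  say("stage grow: pool of %d models", length(pool))

  rp <- score_pool(pool, target, dielec, top_fraction, first_n)
  rp <- select_representative(rp)
  rep_model <- rp$models[[as.character(rp$representative)]]
  say("stage select: representative model %d of top set size %d",
      rp$representative, length(rp$top_set))

  rmsd <- NULL
  if (!is.null(reference)) {
    rmsd <- list(
      rmsd_full = ligand_rmsd(rep_model, reference, "full"),
      rmsd_first = ligand_rmsd(rep_model, reference, "first_n", first_n),
      seed_rmsd = tryCatch(
        seed_pose_rmsd(reps[[1]]$structure, reference, seed_spec),
        error = function(e) NA_real_))
    per_model <- vapply(rp$table$model_id, function(id) c(
      ligand_rmsd(rp$models[[as.character(id)]], reference, "full"),
      ligand_rmsd(rp$models[[as.character(id)]], reference, "first_n",
                  first_n)), numeric(2))
    rmsd$rmsd_best_full <- min(per_model[1, ])
    rmsd$rmsd_best_first <- min(per_model[2, ])
    rmsd$per_model <- data.frame(model_id = rp$table$model_id,
                                 rmsd_full = per_model[1, ],
                                 rmsd_first = per_model[2, ],
                                 score = rp$table$E_inter_first)
  }

  run <- structure(list(
    target = target, sequence = sequence, seed_spec = seed_spec,
    box = box, seed_poses = poses, seed_ranks = reps, pool_size =
      length(pool), ranked = rp, representative = rep_model,
    energy = interaction_energy(rep_model, target, dielec, first_n),
    rmsd = rmsd,
    config = list(dock = dock_cfg, growth = growth_cfg,
                  dielectric = dielec, max_ranks = max_ranks,
                  cluster_tol = cluster_tol, top_fraction = top_fraction,
                  first_n = first_n, rng_seed = rng_seed),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "seedgrow_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

## Heavy-atom RMSD of a docked seed pose to the matching window of the
## reference peptide (cap atoms excluded).
seed_pose_rmsd <- function(seed_structure, reference, spec) {
  win <- c(spec$start, spec$start + 1)
  s <- seed_structure[seed_structure$resno %in% win, , drop = FALSE]
  r <- reference[reference$resno %in% win, , drop = FALSE]
  ## restrict to atoms present in both (reference may lack OXT/H etc.)
  s <- heavy(s); r <- heavy(r)
  key_s <- paste(s$resno, s$name)
  key_r <- paste(r$resno, r$name)
  common <- intersect(key_s, key_r)
  if (length(common) < 3) stop("too few common seed atoms")
  sqrt(mean(rowSums((coords(s)[match(common, key_s), , drop = FALSE] -
                     coords(r)[match(common, key_r), , drop = FALSE])^2)))
}

#' @export
print.seedgrow_run <- function(x, ...) {
  cat("<seedgrow_run>\n")
  cat(sprintf("  peptide: %s (%d aa), seed window %d:%s\n",
              paste(x$sequence$residues, collapse = ""),
              length(x$sequence$residues),
              x$seed_spec$start, x$seed_spec$residues))
  cat(sprintf("  seed poses: %d (%d rank(s) grown); model pool: %d\n",
              length(x$seed_poses), length(x$seed_ranks), x$pool_size))
  cat(sprintf("  representative: model %d (top set of %d), E_inter first %d = %.2f kcal/mol\n",
              x$ranked$representative, length(x$ranked$top_set),
              x$config$first_n, x$energy$first_n_total))
  if (!is.null(x$rmsd))
    cat(sprintf("  RMSD to reference: %.2f (full), %.2f (first %d)\n",
                x$rmsd$rmsd_full, x$rmsd$rmsd_first, x$config$first_n))
  invisible(x)
}

#' @export
summary.seedgrow_run <- function(object, ...) {
  print(object)
  cat("\nper-residue energy of the representative:\n")
  print(object$energy$per_residue, digits = 3)
  cat("\ntop of the ranking table:\n")
  print(utils::head(object$ranked$table), digits = 4)
  invisible(object)
}

## Write the run's outputs: solution complex, tables and a manifest.
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(run$representative, file.path(dir, "solution_ligand.pdb"))
  utils::write.table(run$ranked$table, file.path(dir, "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$energy$per_residue,
                     file.path(dir, "per_residue_energy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$rmsd))
    writeLines(sprintf("%s\t%.4f",
                       c("rmsd_full", "rmsd_first", "seed_rmsd",
                         "rmsd_best_full", "rmsd_best_first"),
                       c(run$rmsd$rmsd_full, run$rmsd$rmsd_first,
                         run$rmsd$seed_rmsd, run$rmsd$rmsd_best_full,
                         run$rmsd$rmsd_best_first)),
               file.path(dir, "rmsd_report.tsv"))
  manifest <- c(
    sprintf("rng_seed\t%d", run$config$rng_seed),
    sprintf("seed_window\t%d:%s", run$seed_spec$start,
            run$seed_spec$residues),
    sprintf("n_seed_poses\t%d", length(run$seed_poses)),
    sprintf("n_ranks\t%d", length(run$seed_ranks)),
    sprintf("pool_size\t%d", run$pool_size),
    sprintf("top_set_size\t%d", length(run$ranked$top_set)),
    sprintf("representative\t%d", run$ranked$representative),
    sprintf("elapsed_s\t%.1f", run$elapsed))
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
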