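## Evaluation against reference complexes: target superposition,
## heavy-atom ligand RMSD and benchmark summary statistics.

#' Superpose a model complex onto a reference complex by the target
#'
#' Least-squares (Kabsch) superposition of the model target's C-alpha
#' atoms onto the reference target's, matched by residue number.  The
#' resulting rigid transform is applied to the whole model complex
#' (target and ligand), so that ligand RMSDs can be measured in the
#' reference frame.
#'
#' @param model_complex,reference_complex lists with elements `target` and
#'   `ligand` (`pepstruct` objects).
#' @return list: `transform` (rotation, translation, fit rmsd over target
#'   C-alphas) and `complex` (the transformed model complex).
#' @export
superpose_targets <- function(model_complex, reference_complex) {
  mt <- model_complex$target
  rt <- reference_complex$target
  mca <- mt[mt$name == "CA" & !mt$is_h, , drop = FALSE]
  rca <- rt[rt$name == "CA" & !rt$is_h, , drop = FALSE]
  common <- intersect(mca$resno, rca$resno)
  if (length(common) < 3)
    stop("fewer than 3 common C-alpha atoms between targets")
  mi <- match(common, mca$resno)
  ri <- match(common, rca$resno)
  fit <- kabsch_fit(coords(mca)[mi, , drop = FALSE],
                    coords(rca)[ri, , drop = FALSE])
  out <- model_complex
  out$target <- set_coords(mt, apply_transform(coords(mt), fit))
  out$ligand <- set_coords(model_complex$ligand,
                           apply_transform(coords(model_complex$ligand),
                                           fit))
  list(transform = fit, complex = out)
}

#' Heavy-atom RMSD between a model ligand and the reference ligand
#'
#' Root-mean-square deviation over matched heavy atoms (residue number +
#' atom name), including side chains; superposition must already have been
#' applied (the two ligands are compared in a common frame).
#'
#' @param model_ligand,reference_ligand `pepstruct` objects.
#' @param subset `"full"` for all residues or `"first_n"` for the
#'   N-terminal `first_n` residues.
#' @param first_n number of N-terminal residues for `subset = "first_n"`;
#'   default 5.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(model_ligand, reference_ligand,
                        subset = c("full", "first_n"), first_n = 5) {
  subset <- match.arg(subset)
  m <- heavy(model_ligand)
  r <- heavy(reference_ligand)
  if (subset == "first_n") {
    mres <- sort(unique(m$resno))
    rres <- sort(unique(r$resno))
    m <- m[m$resno %in% mres[seq_len(min(first_n, length(mres)))], ,
           drop = FALSE]
    r <- r[r$resno %in% rres[seq_len(min(first_n, length(rres)))], ,
           drop = FALSE]
  }
  key_m <- paste(m$resno, m$name)
  key_r <- paste(r$resno, r$name)
  idx <- match(key_r, key_m)
  if (anyNA(idx) || length(key_r) != length(key_m)) {
    unmatched <- c(setdiff(key_r, key_m), setdiff(key_m, key_r))
    stop("atom correspondence mismatch; unmatched atoms: ",
         paste(unmatched, collapse = ", "))
  }
  sqrt(mean(rowSums((coords(m)[idx, , drop = FALSE] - coords(r))^2)))
}

#' Benchmark statistics over evaluated systems
#'
#' For each system, computes `RMSD_best` (the minimum RMSD over all its
#' binding modes) and `RMSD_top` (the RMSD of the mode with the best,
#' i.e. lowest, score), for the full ligand and the first-residues subset;
#' then summarises mean and standard deviation across systems.
#'
#' @param per_system_results named list; each element a data.frame with
#'   columns `rmsd_full`, `rmsd_first`, `score` (one row per binding
#'   mode).  Systems with no rows are excluded with a warning.
#' @return list: `per_system` (data.frame of RMSD_best/RMSD_top per
#'   system) and `summary` (mean/sd per metric).
#' @export
benchmark_stats <- function(per_system_results) {
  keep <- vapply(per_system_results, NROW, integer(1)) > 0
  if (any(!keep))
    warning("excluding empty system(s): ",
            paste(names(per_system_results)[!keep], collapse = ", "))
  per_system_results <- per_system_results[keep]
  if (length(per_system_results) == 0) stop("no evaluable systems")
  per <- do.call(rbind, lapply(names(per_system_results), function(nm) {
    d <- per_system_results[[nm]]
    top <- which.min(d$score)
    data.frame(system = nm,
               rmsd_best_full = min(d$rmsd_full),
               rmsd_top_full = d$rmsd_full[top],
               rmsd_best_first = min(d$rmsd_first),
               rmsd_top_first = d$rmsd_first[top],
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  metrics <- c("rmsd_best_full", "rmsd_top_full",
               "rmsd_best_first", "rmsd_top_first")
  summ <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(per) > 1) stats::sd(per[[m]]) else 0, numeric(1)))
  rownames(summ) <- NULL
  list(per_system = per, summary = summ)
}
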