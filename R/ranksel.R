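## Pool scoring, ranking and representative selection.

#' Score and rank a model pool
#'
#' Computes the full-ligand and first-`first_n`-residue intermolecular
#' interaction energies (with their Lennard-Jones and Coulomb components)
#' for every model and ranks the pool by the first-`first_n` energy,
#' most negative first.  Models that cannot be scored (unparameterised
#' atoms) are dropped with a warning.
#'
#' @param pool list of `pepstruct` models, or of
#'   `list(structure, seed_rank, model_id)` entries as produced by
#'   [grow_from_all_ranks()].
#' @param target parameterised receptor.
#' @param p a [dielectric_params()] object.
#' @param top_fraction fraction of the pool forming the top set
#'   (default 0.01).
#' @param first_n number of N-terminal ligand residues in the selection
#'   score (default 5).
#' @return object of class `ranked_pool`: list with `models` (named by
#'   model id), `table` (one row per model, ranked), `top_fraction`,
#'   `first_n`; `top_set` and `representative` are filled by
#'   [select_representative()].
#' @export
score_pool <- function(pool, target, p = dielectric_params(),
                       top_fraction = 0.01, first_n = 5) {
  stopifnot(length(pool) >= 1)
  norm <- lapply(seq_along(pool), function(i) {
    el <- pool[[i]]
    if (inherits(el, "pepstruct"))
      list(structure = el, seed_rank = NA_integer_, model_id = i)
    else el
  })
  rows <- list()
  models <- list()
  for (el in norm) {
    rep <- tryCatch(interaction_energy(el$structure, target, p, first_n),
                    error = function(e) {
                      warning("model ", el$model_id, " skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(rep)) next
    sel <- rep$per_residue$residue <= first_n
    rows[[length(rows) + 1]] <- data.frame(
      model_id = el$model_id, seed_rank = el$seed_rank,
      E_LJ_full = unname(rep$total["E_LJ"]),
      E_Coulomb_full = unname(rep$total["E_Coulomb"]),
      E_inter_full = unname(rep$total["E_inter"]),
      E_LJ_first = sum(rep$per_residue$E_LJ[sel]),
      E_Coulomb_first = sum(rep$per_residue$E_Coulomb[sel]),
      E_inter_first = rep$first_n_total)
    models[[as.character(el$model_id)]] <- el$structure
  }
  if (length(rows) == 0) stop("no scorable models in pool")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$E_inter_first, tab$model_id), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(models = models, table = tab,
                 top_fraction = top_fraction, first_n = first_n,
                 top_set = NULL, representative = NULL),
            class = "ranked_pool")
}

#' @export
print.ranked_pool <- function(x, ...) {
  cat(sprintf("<ranked_pool> %d models, ranked by E_inter over first %d residues\n",
              nrow(x$table), x$first_n))
  print(utils::head(x$table, 5))
  if (!is.null(x$representative))
    cat("representative: model", x$representative, "\n")
  invisible(x)
}

top_set_size <- function(n, top_fraction) max(1L, ceiling(top_fraction * n))

#' Select the representative model from the top fraction
#'
#' Takes the best `ceiling(top_fraction * n)` models (at least one) by the
#' ranking score, averages their heavy-atom coordinates atom-wise in the
#' common target frame (no superposition), and returns the member closest
#' to that mean by heavy-atom RMSD.  Ties break to the lowest model id.
#'
#' @param rp a scored `ranked_pool`.
#' @return the `ranked_pool` with `top_set` (model ids) and
#'   `representative` (model id) filled in.
#' @export
select_representative <- function(rp) {
  stopifnot(inherits(rp, "ranked_pool"))
  n <- nrow(rp$table)
  if (n == 0) stop("empty pool")
  k <- top_set_size(n, rp$top_fraction)
  top_ids <- rp$table$model_id[seq_len(k)]
  xyz_of <- function(id) {
    s <- rp$models[[as.character(id)]]
    coords(heavy(s))
  }
  ref <- rp$models[[as.character(top_ids[1])]]
  ref_key <- paste(heavy(ref)$resno, heavy(ref)$name)
  mats <- lapply(top_ids, function(id) {
    s <- heavy(rp$models[[as.character(id)]])
    key <- paste(s$resno, s$name)
    if (!identical(key, ref_key)) {
      idx <- match(ref_key, key)
      if (anyNA(idx))
        stop("heterogeneous atom composition in top set; cannot average")
      coords(s)[idx, , drop = FALSE]
    } else coords(s)
  })
  mean_xyz <- Reduce(`+`, mats) / length(mats)
  rmsd_to_mean <- vapply(mats, function(m)
    sqrt(mean(rowSums((m - mean_xyz)^2))), numeric(1))
  rp$top_set <- top_ids
  rp$representative <- top_ids[which.min(rmsd_to_mean)]
  rp
}

#' Re-rank a scored pool by a score component
#'
#' Reorders the same pool under an alternative ranking key, for ablation
#' comparisons of the combined energy against its components.
#'
#' @param rp a scored `ranked_pool`.
#' @param key `"E_inter"` (the default combined score), `"LJ_only"` or
#'   `"Coulomb_only"`; all act on the first-`first_n`-residue energies.
#' @return integer vector of model ids, best first.
#' @export
ranking_ablation <- function(rp, key = c("E_inter", "LJ_only",
                                         "Coulomb_only")) {
  key <- match.arg(key)
  col <- switch(key, E_inter = "E_inter_first", LJ_only = "E_LJ_first",
                Coulomb_only = "E_Coulomb_first")
  tab <- rp$table
  tab$model_id[order(tab[[col]], tab$model_id)]
}
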