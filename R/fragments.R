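## Peptide sequences, dipeptide fragment enumeration and seed selection.

#' Peptide sequence with optional residue modifications
#'
#' @param x one-letter amino-acid string (e.g. `"ARTKQTARKSTGGKA"`, the
#'   N-terminal tail of histone H3).
#' @param modifications named character vector mapping 1-based positions to
#'   modification tags; currently `"me3"` on K (trimethyl-lysine) is
#'   supported, e.g. `c("4" = "me3")` for H3K4me3.
#' @return object of class `peptide_seq`.
#' @export
peptide_sequence <- function(x, modifications = NULL) {
  letters1 <- strsplit(toupper(x), "")[[1]]
  if (length(letters1) < 2) stop("peptide sequence must have length >= 2")
  if (!all(letters1 %in% names(.aa3)))
    typing_error(sprintf("unknown residue letter(s): %s",
                         paste(unique(letters1[!letters1 %in% names(.aa3)]),
                               collapse = ", ")))
  mods <- list()
  if (!is.null(modifications)) {
    pos <- as.integer(names(modifications))
    if (any(is.na(pos)) || any(pos < 1 | pos > length(letters1)))
      stop("modification positions out of range")
    for (i in seq_along(pos)) {
      tag <- modifications[[i]]
      if (!identical(tag, "me3"))
        stop("unsupported modification tag: ", tag)
      if (letters1[pos[i]] != "K")
        stop("me3 modification only supported on K")
      mods[[as.character(pos[i])]] <- tag
    }
  }
  structure(list(residues = letters1, modifications = mods),
            class = "peptide_seq")
}

#' @export
print.peptide_seq <- function(x, ...) {
  tags <- if (length(x$modifications))
    paste0(" [", paste(names(x$modifications),
                       unlist(x$modifications), sep = ":", collapse = ", "),
           "]") else ""
  cat(sprintf("<peptide_seq> %s (%d aa)%s\n",
              paste(x$residues, collapse = ""), length(x$residues), tags))
  invisible(x)
}

## Three-letter residue codes, applying modifications (K+me3 -> M3K).
seq_res3 <- function(seq) {
  r3 <- unname(.aa3[seq$residues])
  for (pos in names(seq$modifications))
    if (seq$modifications[[pos]] == "me3")
      r3[as.integer(pos)] <- "M3K"
  r3
}

new_fragment_spec <- function(start, res_letters, res3, n_cap, c_cap) {
  structure(list(start = start, residues = paste(res_letters, collapse = ""),
                 res3 = res3, n_cap = n_cap, c_cap = c_cap),
            class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %d:%s  n_cap=%s c_cap=%s\n",
              x$start, x$residues, x$n_cap, x$c_cap))
  invisible(x)
}

#' Enumerate capped dipeptide fragments of a peptide
#'
#' Slides a 2-residue window along the N-terminal part of the sequence.
#' Each cut is made through the amide bond; cut ends are blocked with
#' acetyl (N-side) and N-methyl-amide (C-side) groups, except that the
#' window starting at position 1 keeps its genuine free N-terminus.
#'
#' @param seq a [peptide_sequence()].
#' @param window_count number of windows, starting at positions
#'   `1..window_count`; defaults to 9 (or `length - 1` for shorter
#'   peptides).
#' @return list of `fragment_spec` objects.
#' @export
enumerate_dipeptides <- function(seq, window_count = NULL) {
  n <- length(seq$residues)
  if (is.null(window_count)) window_count <- min(9, n - 1)
  if (n < window_count + 1)
    stop("sequence too short for ", window_count, " dipeptide windows")
  r3 <- seq_res3(seq)
  lapply(seq_len(window_count), function(s) {
    new_fragment_spec(
      start = s,
      res_letters = seq$residues[c(s, s + 1)],
      res3 = r3[c(s, s + 1)],
      n_cap = if (s == 1) "none" else "acetyl",
      c_cap = "nme")
  })
}

#' Build the 3D structure of a capped dipeptide fragment
#'
#' Constructs the fragment in an ideal-geometry extended conformation
#' (phi = -120, psi = 120, omega = 180, anti side chains) with its capping
#' groups; no force-field minimisation is applied.
#'
#' @param spec a `fragment_spec` from [enumerate_dipeptides()].
#' @param parameterise assign charges/van der Waals parameters; default TRUE.
#' @return a `pepstruct` of the capped fragment, residue numbers matching
#'   the fragment's position in the parent peptide.
#' @export
build_fragment <- function(spec, parameterise = TRUE) {
  s <- build_peptide(spec$res3,
                     n_cap = if (spec$n_cap == "acetyl") "acetyl" else "none",
                     c_cap = if (spec$c_cap %in% c("nme", "N-methyl-amide"))
                       "nme" else "none",
                     start_resno = spec$start)
  if (parameterise) s <- assign_parameters(s)
  s
}

#' Select the seed window from the per-residue energy profile
#'
#' Given one strong holo complex, computes the per-residue interaction
#' energy of the bound peptide and returns the dipeptide window with the
#' most negative summed energy (ties broken to the smallest start).
#'
#' @param ligand,target parameterised `pepstruct` objects of a holo complex.
#' @param p a [dielectric_params()] object.
#' @param seq optional [peptide_sequence()] of the ligand (used to label the
#'   returned window); defaults to the ligand's residue sequence.
#' @param window_count number of candidate windows; default covers the
#'   enumeration range.
#' @return a `fragment_spec`.
#' @export
select_seed_by_energy <- function(ligand, target, p = dielectric_params(),
                                  seq = NULL, window_count = NULL) {
  rep <- interaction_energy(ligand, target, p)
  e <- rep$per_residue$E_inter
  n <- length(e)
  if (is.null(seq)) {
    ## map 3-letter back to 1-letter (M3K reads as K)
    r3 <- rep$per_residue$resid
    letters1 <- vapply(r3, function(code) {
      if (code == "M3K") return("K")
      hit <- names(.aa3)[.aa3 == code]
      if (length(hit) == 0) typing_error(paste("unknown residue", code))
      hit
    }, character(1))
    mods <- which(r3 == "M3K")
    seq <- peptide_sequence(paste(letters1, collapse = ""),
                            if (length(mods))
                              stats::setNames(rep("me3", length(mods)),
                                              as.character(mods)))
  }
  if (is.null(window_count)) window_count <- min(9, n - 1)
  frags <- enumerate_dipeptides(seq, window_count)
  sums <- vapply(seq_len(window_count), function(s) e[s] + e[s + 1],
                 numeric(1))
  frags[[which.min(sums)]]   # which.min ties break to the smallest index
}

#' Select the seed window by full-pipeline RMSD
#'
#' Runs the whole dock-and-grow pipeline once per candidate window against a
#' holo complex with a known reference peptide pose, and returns the
#' candidate whose selected representative has the lowest RMSD to the
#' reference (the `RMSD_top` criterion).  Candidates whose pipeline run
#' fails are skipped with a warning.
#'
#' @param holo list with elements `target` and `ligand` (the reference
#'   experimental peptide pose), both parameterised `pepstruct`s.
#' @param candidates list of `fragment_spec` objects.
#' @param seq [peptide_sequence()] of the full peptide.
#' @param ... further arguments passed to [run_pipeline()].
#' @return list: `spec` (winning `fragment_spec`), `rmsd_top` (named vector
#'   over candidates, NA for failures).
#' @export
select_seed_by_rmsd <- function(holo, candidates, seq, ...) {
  stopifnot(length(candidates) >= 1)
  rmsd_top <- rep(NA_real_, length(candidates))
  names(rmsd_top) <- vapply(candidates, function(cs)
    paste0(cs$start, ":", cs$residues), character(1))
  for (i in seq_along(candidates)) {
    res <- tryCatch(
      run_pipeline(target = holo$target, sequence = seq,
                   seed_spec = candidates[[i]],
                   reference = holo$ligand, ...),
      error = function(e) {
        warning("candidate ", names(rmsd_top)[i], " failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(res) && !is.null(res$rmsd))
      rmsd_top[i] <- res$rmsd$rmsd_full
  }
  if (all(is.na(rmsd_top))) stop("all candidate seeds failed")
  list(spec = candidates[[which.min(rmsd_top)]], rmsd_top = rmsd_top)
}
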