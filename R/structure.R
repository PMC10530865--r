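## Molecular structure container and PDB/mol2 input-output.
##
## A `pepstruct` is a data.frame subclass with one row per atom and columns:
##   serial   integer atom serial
##   name     PDB atom name (e.g. "CA", "OG1")
##   element  one-letter element symbol
##   resid    3-letter residue name
##   chain    chain identifier
##   resno    residue number (author numbering when read from file)
##   x, y, z  coordinates, Angstrom
##   charge   partial charge, elementary-charge units (NA until assigned)
##   radius   van der Waals radius R_i, Angstrom (NA until assigned)
##   eps      well depth eps_i, kcal/mol (NA until assigned)
##   is_h     logical, hydrogen flag

.pep_cols <- c("serial", "name", "element", "resid", "chain", "resno",
               "x", "y", "z", "charge", "radius", "eps", "is_h")

new_pepstruct <- function(df) {
  for (col in .pep_cols)
    if (!col %in% names(df))
      df[[col]] <- switch(col, charge = , radius = , eps = NA_real_,
                          is_h = df$element == "H", NA)
  df <- df[, .pep_cols]
  rownames(df) <- NULL
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  class(df) <- c("pepstruct", "data.frame")
  df
}

#' @export
print.pepstruct <- function(x, ...) {
  cat(sprintf("<pepstruct> %d atoms (%d heavy), %d residues, chain(s): %s\n",
              nrow(x), sum(!x$is_h), nrow(residues(x)),
              paste(unique(x$chain), collapse = ",")))
  if (all(is.na(x$charge))) cat("  parameters: unassigned\n")
  else cat(sprintf("  parameters assigned; net charge %+.3f e\n",
                   sum(x$charge, na.rm = TRUE)))
  invisible(x)
}

#' Coordinate matrix of a structure
#' @param s a `pepstruct`.
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(s) as.matrix(s[, c("x", "y", "z")])

set_coords <- function(s, xyz) {
  s$x <- xyz[, 1]; s$y <- xyz[, 2]; s$z <- xyz[, 3]
  s
}

#' Residue table of a structure
#' @param s a `pepstruct`.
#' @return data.frame of unique (chain, resno, resid) in order of appearance.
#' @export
residues <- function(s) {
  key <- paste(s$chain, s$resno, sep = "|")
  idx <- !duplicated(key)
  data.frame(chain = s$chain[idx], resno = s$resno[idx],
             resid = s$resid[idx], stringsAsFactors = FALSE)
}

heavy <- function(s) s[!s$is_h, , drop = FALSE]

#' Read a molecular structure from a PDB or mol2 file
#'
#' Atom records are returned in file order.  mol2 partial charges populate
#' the `charge` column; PDB files leave charges unassigned (use
#' [assign_parameters()]).
#'
#' @param path path to the file.
#' @param format `"pdb"` or `"mol2"`; default guesses from the extension.
#' @return a `pepstruct`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mol2")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- tryCatch(
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
      error = function(e) stop("PDB parse error in '", path, "': ",
                               conditionMessage(e)))
    a <- pdb$atom
    elem <- a$elesy
    blank <- is.na(elem) | !nzchar(trimws(elem))
    elem[blank] <- residue_elements(trimws(a$elety[blank]))
    elem <- trimws(elem)
    df <- data.frame(
      serial = a$eleno, name = trimws(a$elety), element = elem,
      resid = trimws(a$resid), chain = ifelse(is.na(a$chain), " ", a$chain),
      resno = a$resno, x = a$x, y = a$y, z = a$z,
      charge = NA_real_, radius = NA_real_, eps = NA_real_,
      is_h = elem == "H",
      stringsAsFactors = FALSE)
    attr(df, "record_type") <- a$type
    attr(df, "altloc") <- a$alt
    new_pepstruct(df)
  } else {
    m <- tryCatch(bio3d::read.mol2(path),
                  error = function(e) stop("mol2 parse error in '", path,
                                           "': ", conditionMessage(e)))
    a <- m$atom
    # SYBYL atom type "C.3", "N.am", ... -> element before the dot.
    elem <- toupper(sub("\\..*$", "", a$elety))
    known <- c("C", "N", "O", "S", "H", "P")
    if (!all(elem %in% known))
      typing_error(sprintf("unknown element(s) in mol2: %s",
                           paste(unique(elem[!elem %in% known]),
                                 collapse = ", ")))
    resid3 <- toupper(substr(gsub("[0-9]+$", "", a$resid), 1, 3))
    df <- data.frame(
      serial = a$eleno, name = trimws(a$elena), element = elem,
      resid = resid3, chain = " ", resno = a$resno,
      x = a$x, y = a$y, z = a$z,
      charge = a$charge, radius = NA_real_, eps = NA_real_,
      is_h = elem == "H",
      stringsAsFactors = FALSE)
    new_pepstruct(df)
  }
}

#' Write a structure to a PDB or mol2 file
#'
#' PDB coordinates are written at the standard 3-decimal precision.  mol2
#' output carries the `charge` column; bonds are inferred from interatomic
#' distances.
#'
#' @param s a `pepstruct`.
#' @param path output path.
#' @param format `"pdb"` or `"mol2"`; default guesses from the extension.
#' @export
write_structure <- function(s, path, format = c("auto", "pdb", "mol2")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "pdb"
  if (format == "pdb") {
    chain <- ifelse(s$chain == " ", NA, s$chain)
    bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(s))),
                     resno = s$resno, resid = s$resid, eleno = s$serial,
                     elety = s$name, chain = chain, elesy = s$element,
                     verbose = FALSE)
  } else {
    write_mol2(s, path)
  }
  invisible(path)
}

## Minimal TRIPOS mol2 writer; bonds inferred from distance (<1.9 A between
## heavy atoms, <1.25 A to hydrogens, S-containing pairs up to 2.1 A).
write_mol2 <- function(s, path) {
  xyz <- coords(s)
  n <- nrow(s)
  bonds <- NULL
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    lim <- outer(ifelse(s$is_h, 1.25, ifelse(s$element == "S", 2.1, 1.9)),
                 ifelse(s$is_h, 1.25, ifelse(s$element == "S", 2.1, 1.9)),
                 pmin)
    hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
    hit <- hit[!(s$is_h[hit[, 1]] & s$is_h[hit[, 2]]), , drop = FALSE]
    bonds <- hit
  }
  q <- ifelse(is.na(s$charge), 0, s$charge)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@<TRIPOS>MOLECULE", "seedgrow",
               sprintf("%d %d 1", n, NROW(bonds)),
               "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM"), con)
  writeLines(sprintf("%6d %-6s %9.4f %9.4f %9.4f %-5s %4d %-6s %8.4f",
                     seq_len(n), s$name, s$x, s$y, s$z,
                     sybyl_type(s), s$resno,
                     paste0(s$resid, s$resno), q), con)
  writeLines("@<TRIPOS>BOND", con)
  if (NROW(bonds) > 0)
    writeLines(sprintf("%5d %5d %5d 1", seq_len(NROW(bonds)),
                       bonds[, 1], bonds[, 2]), con)
  invisible(path)
}

sybyl_type <- function(s) {
  ifelse(s$element == "H", "H",
  ifelse(s$element == "S", "S.3",
  ifelse(s$element == "O" & s$name %in% c("O", "OD1", "OE1", "OXT"), "O.2",
  ifelse(s$element == "O", "O.3",
  ifelse(s$element == "N", "N.am",
  ifelse(s$name %in% c("C", "CG", "CD", "CZ") &
           s$resid %in% c("PHE", "TYR", "TRP", "HIS", "ARG",
                          "ASP", "GLU", "ASN", "GLN"), "C.2",
  ifelse(s$name == "C", "C.2", "C.3")))))))
}

#' Assign force-field parameters and template charges
#'
#' Fills `radius`/`eps` for every atom from the shipped united-atom van der
#' Waals table (keyed by element) and fills missing charges from the shipped
#' per-residue charge template.  Charges already present (e.g. read from a
#' mol2 file) are kept.
#'
#' @param s a `pepstruct` of standard amino-acid residues (plus ACE/NME caps
#'   and trimethyl-lysine M3K).
#' @return the structure with `charge`, `radius` and `eps` populated.
#' @export
assign_parameters <- function(s) {
  vdw <- vdw_for_element(s$element)
  s$radius <- vdw$radius
  s$eps <- vdw$eps
  need <- which(is.na(s$charge))
  if (length(need) > 0) {
    res <- residues(s)
    ## Identify terminal residues per chain (caps excluded from termini).
    pos_of <- function(ch, rn) {
      chain_res <- res[res$chain == ch & !res$resid %in% c("ACE", "NME"), ]
      if (nrow(chain_res) == 0) return("internal")
      first <- chain_res$resno[1]
      last <- chain_res$resno[nrow(chain_res)]
      ## An ACE cap before the first residue suppresses the free N-terminus.
      has_ace <- any(res$resid == "ACE" & res$chain == ch)
      has_nme <- any(res$resid == "NME" & res$chain == ch)
      if (rn == first && !has_ace) "nterm"
      else if (rn == last && !has_nme) "cterm"
      else "internal"
    }
    pos_cache <- new.env(parent = emptyenv())
    for (i in need) {
      key <- paste(s$chain[i], s$resno[i])
      pos <- get0(key, pos_cache)
      if (is.null(pos)) {
        pos <- pos_of(s$chain[i], s$resno[i])
        assign(key, pos, pos_cache)
      }
      s$charge[i] <- template_charge(s$resid[i], s$name[i], pos)
    }
  }
  s
}

#' Prepare a protein target for docking
#'
#' Applies the standard receptor preparation: keep only the first protein
#' chain (first chain in file order containing at least one standard amino
#' acid), drop all non-protein records (waters, ions, other heteroatoms),
#' keep only blank/'A' alternate locations, strip any hydrogens present and
#' add polar hydrogens (on N/O/S donors) at ideal geometry, then assign
#' charges and van der Waals parameters.
#'
#' @param s a `pepstruct` read from a PDB file.
#' @return the prepared, parameterised target structure.
#' @export
prepare_target <- function(s) {
  alt <- attr(s, "altloc")
  if (!is.null(alt) && length(alt) == nrow(s)) {
    keep <- is.na(alt) | alt %in% c("", " ", "A")
    s <- s[keep, , drop = FALSE]
  }
  prot <- s$resid %in% .standard_residues
  if (!any(prot))
    stop(errorCondition("no protein chain found in structure",
                        class = c("seedgrow_no_protein_error", "error")))
  first_chain <- s$chain[which(prot)[1]]
  s <- s[s$chain == first_chain & prot, , drop = FALSE]
  s <- s[!s$is_h, , drop = FALSE]          # rebuild hydrogens from scratch
  s <- add_polar_hydrogens(s)
  s$serial <- seq_len(nrow(s))
  assign_parameters(new_pepstruct(as.data.frame(s)))
}

## Add polar hydrogens at ideal geometry using the shipped topology
## templates.  Backbone amide H uses the preceding residue's C/CA; the chain
## N-terminus receives a neutral NH2 (H1/H2); C-terminal OXT (if present)
## receives HXT.  Hydrogens whose reference atoms are missing are skipped.
add_polar_hydrogens <- function(s) {
  res <- residues(s)
  out <- list(as.data.frame(s))
  get_xyz <- function(rn, nm) {
    i <- which(s$resno == rn & s$name == nm)
    if (length(i) == 0) return(NULL)
    c(s$x[i[1]], s$y[i[1]], s$z[i[1]])
  }
  h_row <- function(name, xyz, resid, chain, resno)
    data.frame(serial = NA_integer_, name = name, element = "H",
               resid = resid, chain = chain, resno = resno,
               x = xyz[1], y = xyz[2], z = xyz[3],
               charge = NA_real_, radius = NA_real_, eps = NA_real_,
               is_h = TRUE, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(res))) {
    rn <- res$resno[k]; rt <- res$resid[k]; ch <- res$chain[k]
    if (!rt %in% .standard_residues) next
    N <- get_xyz(rn, "N"); CA <- get_xyz(rn, "CA"); C <- get_xyz(rn, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k == 1) {
      if (rt != "PRO") {
        ## neutral N-terminal amine: two H staggered about the N
        out[[length(out) + 1]] <- h_row("H1",
          place_atom(C, CA, N, 1.01, 109.5, 60), rt, ch, rn)
        out[[length(out) + 1]] <- h_row("H2",
          place_atom(C, CA, N, 1.01, 109.5, 180), rt, ch, rn)
      }
    } else if (rt != "PRO") {
      pc <- get_xyz(res$resno[k - 1], "C")
      pca <- get_xyz(res$resno[k - 1], "CA")
      if (is.null(pca)) pca <- get_xyz(res$resno[k - 1], "CH3")
      if (!is.null(pc) && !is.null(pca))
        out[[length(out) + 1]] <- h_row("HN",
          place_atom(pca, pc, N, .bb_geom$n_h, .bb_geom$ang_c_n_h, 0),
          rt, ch, rn)
    }
    ## side-chain polar hydrogens from the topology template
    topo <- .sidechain_topology[[rt]]
    if (!is.null(topo)) {
      have <- function(nm) !is.null(get_xyz(rn, nm))
      for (entry in topo) {
        if (substr(entry$name, 1, 1) != "H") next
        if (have(entry$name)) next
        refs <- lapply(entry$refs, function(nm) get_xyz(rn, nm))
        if (any(vapply(refs, is.null, logical(1)))) next
        dih <- entry$dihedral
        if (is.list(dih)) dih <- .chi_states[1] + dih$offset
        out[[length(out) + 1]] <- h_row(entry$name,
          place_atom(refs[[1]], refs[[2]], refs[[3]],
                     entry$bond, entry$angle, dih), rt, ch, rn)
      }
    }
    ## C-terminal carboxylic acid proton
    OXT <- get_xyz(rn, "OXT")
    if (!is.null(OXT) && k == nrow(res)) {
      out[[length(out) + 1]] <- h_row("HXT",
        place_atom(CA, C, OXT, 0.96, 109.0, 180), rt, ch, rn)
    }
  }
  df <- do.call(rbind, out)
  ## keep atom blocks grouped by residue, hydrogens after their heavies
  ord <- order(match(paste(df$chain, df$resno), paste(res$chain, res$resno)))
  df <- df[ord, , drop = FALSE]
  df$serial <- seq_len(nrow(df))
  new_pepstruct(df)
}
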