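## In-situ peptide growing from a docked dipeptide seed.  The seed's
## residues stay fixed in the target frame; caps are removed and replaced
## by real neighbours; the chain is extended residue by residue (N-ward
## first when the seed is internal, then C-ward) with backbone torsions
## drawn from weighted Ramachandran basins, side chains from a small
## rotamer set, steric rejection against the target and the already-built
## ligand, and greedy selection of the best incremental interaction energy
## among surviving candidates.

#' Growing configuration
#'
#' @param n_models models generated per seed representative (default 100,
#'   the per-step model count of the protocol).
#' @param candidates_per_residue torsion/rotamer draws per added residue.
#' @param clash_factor a candidate heavy atom closer than
#'   `clash_factor * (R_i + R_j)` to a target or non-adjacent ligand heavy
#'   atom is rejected; default 0.7.
#' @param max_retries times a model may be restarted from the seed after a
#'   dead end before being abandoned.
#' @param rng_seed seed for all random draws.
#' @param basins Ramachandran basins as a list of
#'   `list(phi = c(lo, hi), psi = c(lo, hi), weight = w)`; defaults to
#'   alpha/beta/PPII with weights 0.35/0.45/0.20.
#' @return list of class `growth_config`.
#' @export
growth_config <- function(n_models = 100, candidates_per_residue = 8,
                          clash_factor = 0.7, max_retries = 50,
                          rng_seed = 1, basins = NULL) {
  if (is.null(basins))
    basins <- list(
      alpha = list(phi = c(-100, -40), psi = c(-60, -10), weight = 0.35),
      beta  = list(phi = c(-160, -90), psi = c(100, 170), weight = 0.45),
      ppii  = list(phi = c(-90, -55),  psi = c(120, 170), weight = 0.20))
  w <- vapply(basins, `[[`, numeric(1), "weight")
  stopifnot(n_models >= 1, clash_factor > 0, clash_factor < 1,
            abs(sum(w) - 1) < 1e-9)
  structure(list(n_models = n_models,
                 candidates_per_residue = candidates_per_residue,
                 clash_factor = clash_factor, max_retries = max_retries,
                 rng_seed = rng_seed, basins = basins, basin_w = w),
            class = "growth_config")
}

draw_phi_psi <- function(cfg) {
  b <- cfg$basins[[sample.int(length(cfg$basins), 1, prob = cfg$basin_w)]]
  c(phi = stats::runif(1, b$phi[1], b$phi[2]),
    psi = stats::runif(1, b$psi[1], b$psi[2]))
}

draw_chis <- function(restype) {
  k <- .n_chi[[restype]]
  if (k == 0) return(180)
  .chi_states[sample.int(3, k, replace = TRUE, prob = .chi_weights)] +
    stats::rnorm(k, 0, 8)
}

#' Grow the full peptide from a docked seed pose
#'
#' The seed's residues are kept fixed (their coordinates are copied
#' unchanged, so the seed backbone is preserved exactly); capping groups
#' are discarded and replaced by the flanking residues of the full
#' sequence.  The cap heavy atoms also fix the junction torsions: the
#' N-methyl-amide nitrogen marks where the next residue's backbone N
#' attaches and the acetyl carbonyl carbon marks the preceding residue's
#' C, so the first added residue on each side reuses the corresponding
#' torsion instead of sampling it.  Each model is grown independently; a
#' model that dead-ends (no clash-free candidate at some residue) is
#' restarted, up to `cfg$max_retries` restarts per model.
#'
#' @param target parameterised receptor `pepstruct`.
#' @param seed a `pose` (or a `pepstruct`) holding the placed capped
#'   dipeptide.
#' @param full_seq [peptide_sequence()] of the complete peptide.
#' @param spec the `fragment_spec` locating the seed within `full_seq`.
#' @param cfg a [growth_config()].
#' @param p a [dielectric_params()] object.
#' @return list of parameterised full-length `pepstruct` models (length at
#'   most `cfg$n_models`); errors if no model can be grown.
#' @export
grow_peptide <- function(target, seed, full_seq, spec,
                         cfg = growth_config(), p = dielectric_params()) {
  set.seed(cfg$rng_seed)
  seed_s <- if (inherits(seed, "pose")) seed$structure else seed
  res3 <- seq_res3(full_seq)
  n <- length(res3)
  s1 <- spec$start
  s2 <- spec$start + 1
  stopifnot(s2 <= n)

  get_seed <- function(rn, nm) {
    i <- which(seed_s$resno == rn & seed_s$name == nm)
    if (length(i) == 0) NULL else c(seed_s$x[i[1]], seed_s$y[i[1]],
                                    seed_s$z[i[1]])
  }
  ## junction torsions implied by the caps (before the caps are dropped)
  cap_n <- get_seed(s2 + 1, "N")    # NME nitrogen = next residue's N
  ace_c <- get_seed(s1 - 1, "C")    # acetyl carbonyl = previous C
  psi_link <- if (!is.null(cap_n))
    torsion_angle(get_seed(s2, "N"), get_seed(s2, "CA"),
                  get_seed(s2, "C"), cap_n) else NA_real_
  phi_link <- if (!is.null(ace_c))
    torsion_angle(ace_c, get_seed(s1, "N"), get_seed(s1, "CA"),
                  get_seed(s1, "C")) else NA_real_

  seed_keep <- seed_s[seed_s$resno %in% c(s1, s2), , drop = FALSE]
  if (s1 > 1)  # HN of the first seed residue is re-placed after growth
    seed_keep <- seed_keep[!(seed_keep$resno == s1 &
                               seed_keep$name == "HN"), , drop = FALSE]

  tgt_h <- heavy(target)
  txyz <- coords(tgt_h)
  trad <- tgt_h$radius
  t_all <- list(xyz = coords(target), q = target$charge,
                rad = target$radius, eps = target$eps)

  cand_energy <- function(xyz, q, rad, eps) {
    r <- sqrt(dist2_matrix(xyz, t_all$xyz))
    Rij <- outer(rad, t_all$rad, "+")
    eij <- sqrt(outer(eps, t_all$eps))
    inv6 <- r^-6
    lj <- eij * Rij^12 * inv6 * inv6 - 2 * eij * Rij^6 * inv6
    eps_r <- p$A + p$B / (1 + p$k * exp(-p$lam * p$B * r))
    sum(lj) + sum(.coulomb_const * outer(q, t_all$q) / (eps_r * r))
  }

  clash_free <- function(xyz, rad, lig_xyz, lig_rad) {
    lim_t <- cfg$clash_factor * outer(rad, trad, "+")
    if (any(dist2_matrix(xyz, txyz) < lim_t^2)) return(FALSE)
    if (!is.null(lig_xyz) && nrow(lig_xyz) > 0) {
      lim_l <- cfg$clash_factor * outer(rad, lig_rad, "+")
      if (any(dist2_matrix(xyz, lig_xyz) < lim_l^2)) return(FALSE)
    }
    TRUE
  }

  grow_one <- function() {
    entries <- vector("list", n)
    for (rn in c(s1, s2)) {
      rows <- seed_keep[seed_keep$resno == rn, , drop = FALSE]
      entries[[rn]] <- stats::setNames(
        lapply(seq_len(nrow(rows)),
               function(i) c(rows$x[i], rows$y[i], rows$z[i])),
        rows$name)
    }
    lig_heavy <- function(resnos) {
      xyz <- list(); rad <- numeric(0)
      for (rn in resnos) {
        e <- entries[[rn]]
        if (is.null(e)) next
        hn <- names(e)[substr(names(e), 1, 1) != "H"]
        for (nm in hn) xyz[[length(xyz) + 1]] <- e[[nm]]
        rad <- c(rad, vdw_for_element(residue_elements(hn))$radius)
      }
      if (length(xyz) == 0) return(list(xyz = NULL, rad = NULL))
      list(xyz = do.call(rbind, xyz), rad = rad)
    }

    add_residue <- function(i, direction, fixed_link = NA_real_) {
      restype <- res3[i]
      pos <- if (i == 1) "nterm" else if (i == n) "cterm" else "internal"
      far <- setdiff(which(!vapply(entries, is.null, logical(1))),
                     (i - 1):(i + 1))
      lig <- lig_heavy(far)
      best <- NULL
      for (try in seq_len(cfg$candidates_per_residue)) {
        tor <- draw_phi_psi(cfg)
        chis <- draw_chis(restype)
        at <- if (direction == "C") {
          prev <- entries[[i - 1]]
          psi_prev <- if (is.na(fixed_link)) tor["psi"] else fixed_link
          forward_residue_xyz(prev$N, prev$CA, prev$C,
                              psi_prev = psi_prev, phi = tor["phi"],
                              restype = restype, chis = chis)
        } else {
          nxt <- entries[[i + 1]]
          phi_next <- if (is.na(fixed_link)) tor["phi"] else fixed_link
          backward_residue_xyz(nxt$N, nxt$CA, nxt$C,
                               phi_next = phi_next, psi = tor["psi"],
                               restype = restype, chis = chis)
        }
        extra <- at[intersect(names(at), c("O_prev", "HN_next"))]
        own <- at[setdiff(names(at), c("O_prev", "HN_next"))]
        if (direction == "C" && i == n) {
          psi_n <- tor["psi"]  # reuse the basin draw for the carboxylate
          own$O <- place_atom(own$N, own$CA, own$C, .bb_geom$c_o,
                              .bb_geom$ang_ca_c_o, psi_n + 180)
          own$OXT <- place_atom(own$N, own$CA, own$C, 1.252, 117.0, psi_n)
          own$HXT <- place_atom(own$CA, own$C, own$OXT, 0.96, 109.0, 180)
        }
        if (direction == "N" && i == 1 && restype != "PRO") {
          own$H1 <- place_atom(own$C, own$CA, own$N, 1.01, 109.5, 60)
          own$H2 <- place_atom(own$C, own$CA, own$N, 1.01, 109.5, 180)
        }
        hv <- names(own)[substr(names(own), 1, 1) != "H"]
        xyz <- do.call(rbind, own[hv])
        rad <- vdw_for_element(residue_elements(hv))$radius
        if (!clash_free(xyz, rad, lig$xyz, lig$rad)) next
        ## the previous residue's carbonyl O (placed from this psi draw)
        ## must also clear the target
        if (!is.null(extra$O_prev)) {
          lim_o <- cfg$clash_factor * (vdw_for_element("O")$radius + trad)
          if (any(dist2_matrix(matrix(extra$O_prev, 1), txyz) < lim_o^2))
            next
        }
        anames <- names(own)
        q <- vapply(anames, function(nm)
          template_charge(restype, nm, pos), numeric(1))
        vd <- vdw_for_element(residue_elements(anames))
        e_inc <- cand_energy(do.call(rbind, own), q, vd$radius, vd$eps)
        if (is.null(best) || e_inc < best$e)
          best <- list(own = own, extra = extra, e = e_inc)
      }
      best
    }

    ## N-ward first, then C-ward
    for (i in rev(seq_len(s1 - 1))) {
      got <- add_residue(i, "N",
                         fixed_link = if (i == s1 - 1) phi_link
                                      else NA_real_)
      if (is.null(got)) return(NULL)
      entries[[i]] <- got$own
      if (!is.null(got$extra$HN_next) && res3[i + 1] != "PRO" &&
          !"HN" %in% names(entries[[i + 1]]))
        entries[[i + 1]]$HN <- got$extra$HN_next
    }
    for (i in seq(s2 + 1, length.out = n - s2)) {
      got <- add_residue(i, "C",
                         fixed_link = if (i == s2 + 1) psi_link
                                      else NA_real_)
      if (is.null(got)) return(NULL)
      entries[[i]] <- got$own
      if (!is.null(got$extra$O_prev) && !"O" %in% names(entries[[i - 1]]))
        entries[[i - 1]]$O <- got$extra$O_prev
    }
    ## terminal completion when a seed residue is itself terminal
    if (s2 == n && !"OXT" %in% names(entries[[n]])) {
      e <- entries[[n]]
      psi_n <- if (!is.na(psi_link)) psi_link else 120
      entries[[n]]$OXT <- place_atom(e$N, e$CA, e$C, 1.252, 117.0, psi_n)
      entries[[n]]$HXT <- place_atom(e$CA, e$C, entries[[n]]$OXT,
                                     0.96, 109.0, 180)
    }
    if (s1 == 1 && res3[1] != "PRO" && !"H1" %in% names(entries[[1]])) {
      e <- entries[[1]]
      entries[[1]]$H1 <- place_atom(e$C, e$CA, e$N, 1.01, 109.5, 60)
      entries[[1]]$H2 <- place_atom(e$C, e$CA, e$N, 1.01, 109.5, 180)
    }
    ents <- lapply(seq_len(n), function(i)
      list(resno = i, resid = res3[i], atoms = entries[[i]]))
    assign_parameters(order_atoms(assemble_structure(ents, chain = "P")))
  }

  models <- vector("list", cfg$n_models)
  for (m in seq_len(cfg$n_models)) {
    model <- NULL
    for (attempt in seq_len(cfg$max_retries + 1)) {
      model <- grow_one()
      if (!is.null(model)) break
    }
    models[[m]] <- model
  }
  models <- models[!vapply(models, is.null, logical(1))]
  if (length(models) == 0)
    stop("no model could be grown; consider a looser clash_factor")
  models
}

#' Grow model pools from every seed rank
#'
#' Runs [grow_peptide()] once per clustered seed representative, tagging
#' each model with its seed rank.  Per-rank failures are downgraded to
#' warnings so that remaining ranks still contribute.
#'
#' @param target parameterised receptor.
#' @param representatives list of ranked `pose` objects
#'   (from [cluster_and_rank()]).
#' @param full_seq [peptide_sequence()] of the complete peptide.
#' @param spec the seed `fragment_spec`.
#' @param cfg a [growth_config()]; rank r uses `rng_seed + 1000 * r`.
#' @param p a [dielectric_params()] object.
#' @return list of `list(structure, seed_rank, model_id)` entries.
#' @export
grow_from_all_ranks <- function(target, representatives, full_seq, spec,
                                cfg = growth_config(),
                                p = dielectric_params()) {
  stopifnot(length(representatives) >= 1)
  pool <- list()
  for (rep_i in seq_along(representatives)) {
    pose <- representatives[[rep_i]]
    rank <- if (is.na(pose$cluster_rank)) rep_i else pose$cluster_rank
    cfg_r <- cfg
    cfg_r$rng_seed <- cfg$rng_seed + 1000L * rank
    models <- tryCatch(
      grow_peptide(target, pose, full_seq, spec, cfg_r, p),
      error = function(e) {
        warning("growing failed for seed rank ", rank, ": ",
                conditionMessage(e), call. = FALSE)
        list()
      })
    for (m in models)
      pool[[length(pool) + 1]] <- list(structure = m, seed_rank = rank,
                                       model_id = length(pool) + 1L)
  }
  if (length(pool) == 0) stop("no models grown from any seed rank")
  pool
}
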