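# Markov-chain Monte Carlo repacking of a spin label and its neighborhood.
#
# Each step picks a repackable site uniformly at random, draws a rotamer
# from that site's library by prior weight (optionally with wrapped-normal
# off-rotamer perturbation), and accepts with the Metropolis-Hastings
# criterion. Because the proposal draws from the prior weights, the correct
# M-H ratio includes the proposal-prior factor q(old)/q(new); this is the
# default, with plain Metropolis available for comparison. Canonical
# residues use a small bundled backbone-independent rotamer set (chi grids
# with conventional gauche-/trans/gauche+ values) standing in for a full
# backbone-dependent library.

CANONICAL_CHI_DEFS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")))

# chi grids: chi1 gauche-/trans/gauche+ with conventional population order,
# higher chis uniform over the three staggered wells (capped at 27 rotamers).
canonical_rotamer_grid <- function(n_chi) {
  vals <- c(-60, 180, 60)
  w1 <- c(0.5, 0.3, 0.2)
  grids <- rep(list(vals), n_chi)
  g <- as.matrix(expand.grid(grids))
  w <- w1[match(g[, 1], vals)]
  if (n_chi > 1) w <- w / 3^(n_chi - 1)
  colnames(g) <- NULL
  list(chis = g, weights = w / sum(w))
}

# Realize a site's rotamer set as coordinate variants of its current side
# chain. Returns NULL for residues without rotatable chis (GLY/ALA/PRO).
site_rotamer_states <- function(structure, chain, resnum) {
  a <- structure$atoms
  res <- residue_indices(structure, chain, resnum)
  resname <- a$resname[res[1]]
  defs <- CANONICAL_CHI_DEFS[[resname]]
  if (is.null(defs)) return(NULL)
  names_ <- a$name[res]
  quads <- lapply(defs, function(q) {
    i <- match(q, names_)
    if (anyNA(i)) return(NULL)
    res[i]
  })
  if (any(vapply(quads, is.null, TRUE))) return(NULL)
  co <- structure$coords[[1]]
  bonds <- infer_bonds(co[res, , drop = FALSE], a$element[res])
  adj <- adjacency_list(bonds, length(res))
  grid <- canonical_rotamer_grid(length(defs))
  downstream <- lapply(defs, function(q) {
    i2 <- match(q[2], names_); i3 <- match(q[3], names_)
    res[downstream_atoms(adj, i2, i3)]
  })
  list(resname = resname, atoms = res, quads = quads,
       downstream = downstream, chis = grid$chis, weights = grid$weights,
       sidechain = res[!(names_ %in% c("N", "CA", "C", "O"))])
}

apply_chis <- function(coords, quads, downstream, values) {
  for (k in seq_along(quads))
    coords <- set_dihedral(coords, quads[[k]], downstream[[k]], values[k])
  coords
}

default_site_energy <- function(site_co, site_el, env_co, env_el, params)
  pair_lj_energy(site_co, site_el, env_co, env_el, params)

#' MCMC repacking of label and neighboring side chains
#'
#' The repack region comprises the label sites plus every residue with a
#' rotatable side-chain atom within `radius` of any label rotamer atom.
#' Returns the accepted-state trajectory and the relative energy after
#' every step.
#'
#' @param structure a `StructureModel` (single model used).
#' @param labels list of attached `SpinLabel` objects; each label site's
#'   rotamer set is the label's own (aligned) ensemble.
#' @param radius neighborhood radius in Angstrom (default 10).
#' @param n_steps number of MCMC steps (>= 1).
#' @param kT temperature factor in kcal/mol; Inf forces acceptance.
#' @param off_rotamer perturb drawn rotamers by wrapped-normal dihedral noise.
#' @param off_sigma off-rotamer sigma in degrees (default 35).
#' @param seed RNG seed.
#' @param proposal_correction include the q(old)/q(new) proposal-prior
#'   factor (correct Metropolis-Hastings, default) or plain Metropolis.
#' @param store_frames keep accepted-state coordinate snapshots (default
#'   TRUE; switch off for very long runs where only energies/states matter).
#' @param energy_func site energy callback
#'   (site_coords, site_elements, env_coords, env_elements, params) -> kcal/mol.
#' @param params an `lj_params`.
#' @return a `RepackTrajectory`: frames (full-coordinate snapshots of the
#'   initial and every accepted state), energies (relative, one per step),
#'   accepted (logical per step), region, seed.
#' @export
repack <- function(structure, labels, radius = 10, n_steps = 1000,
                   kT = 0.593, off_rotamer = FALSE, off_sigma = 35,
                   seed = NULL, proposal_correction = TRUE,
                   store_frames = TRUE,
                   energy_func = default_site_energy, params = lj_params()) {
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (!length(labels)) stop("repack region is empty: no labels", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  a <- structure$atoms
  co <- structure$coords[[1]]

  # graft rotamer 1 of each label into the structure so label coordinates
  # are part of the system state
  work <- structure
  for (lab in labels)
    work <- mutate_site(work, lab$site$chain, lab$site$resnum, lab, 1)
  a <- work$atoms; co <- work$coords[[1]]

  label_keys <- vapply(labels, function(l) paste(l$site$chain, l$site$resnum), "")
  lab_atoms <- lapply(labels, function(lab) {
    res <- residue_indices(work, lab$site$chain, lab$site$resnum)
    nm <- a$name[res]
    i <- match(lab$atom_names, nm)
    if (anyNA(i)) stop("label atoms not found after grafting", call. = FALSE)
    res[i]
  })

  # region: residues with any side-chain atom within radius of any label
  # rotamer atom (over all rotamers), plus the label sites
  lab_cloud <- do.call(rbind, lapply(labels, function(lab) {
    m <- apply(lab$coords, 3, identity)
    matrix(m, ncol = 3)
  }))
  resid <- unique(a[, c("chain", "resnum", "resname")])
  sites <- list()
  for (k in seq_len(nrow(resid))) {
    keyk <- paste(resid$chain[k], resid$resnum[k])
    is_label <- keyk %in% label_keys
    if (!is_label) {
      if (is.null(CANONICAL_CHI_DEFS[[resid$resname[k]]])) next
      sc <- which(a$chain == resid$chain[k] & a$resnum == resid$resnum[k] &
                    !(a$name %in% c("N", "CA", "C", "O")))
      if (!length(sc)) next
      d2 <- outer(rowSums(co[sc, , drop = FALSE]^2), rowSums(lab_cloud^2), `+`) -
        2 * co[sc, , drop = FALSE] %*% t(lab_cloud)
      if (min(d2) > radius^2) next
      st <- site_rotamer_states(work, resid$chain[k], resid$resnum[k])
      if (is.null(st)) next
      st$kind <- "canonical"
    } else {
      lab <- labels[[match(keyk, label_keys)]]
      idx <- lab_atoms[[match(keyk, label_keys)]]
      st <- list(resname = lab$resname, atoms = idx,
                 rot_coords = lab$coords, weights = lab$weights,
                 sidechain = idx[!(lab$atom_names %in% c("N", "CA", "C", "O"))],
                 sc_sel = which(!(lab$atom_names %in% c("N", "CA", "C", "O"))),
                 dihedral_quads = lapply(lab$dihedral_defs, function(q)
                   idx[match(q, lab$atom_names)]),
                 kind = "label")
      # downstream sets in structure indexing, for off-rotamer moves
      lib_like <- list()
      st$elements <- lab$elements
    }
    st$chain <- resid$chain[k]; st$resnum <- resid$resnum[k]
    st$cur_rot <- NA_integer_
    sites[[length(sites) + 1]] <- st
  }
  if (!length(sites)) stop("repack region is empty", call. = FALSE)
  for (s in sites) if (s$kind == "canonical" && is.null(CANONICAL_CHI_DEFS[[s$resname]]))
    stop("unsupported residue in repack region: ", s$resname, call. = FALSE)

  frames <- list(co)
  energies <- numeric(n_steps)
  accepted <- logical(n_steps)
  states <- matrix(NA_integer_, n_steps, length(sites))
  e_rel <- 0
  water <- a$resname %in% c("HOH", "WAT")

  site_energy <- function(site, coords_now, sc_coords) {
    # exclude the site's own residue: bonded 1-2/1-3 contacts are not clashes
    env_idx <- setdiff(which(!water), site$atoms)
    energy_func(sc_coords, a$element[site$sidechain],
                coords_now[env_idx, , drop = FALSE], a$element[env_idx],
                params)
  }

  for (step in seq_len(n_steps)) {
    si <- sample.int(length(sites), 1)
    s <- sites[[si]]
    if (s$kind == "label") {
      r <- sample.int(length(s$weights), 1, prob = s$weights)
      new_res_co <- s$rot_coords[r, , , drop = TRUE]
      q_new <- s$weights[r]
    } else {
      r <- sample.int(nrow(s$chis), 1, prob = s$weights)
      chis <- s$chis[r, ]
      if (off_rotamer) chis <- wrap_angle(chis + stats::rnorm(length(chis), 0, off_sigma))
      co_try <- apply_chis(co, s$quads, s$downstream, chis)
      new_res_co <- co_try[s$atoms, , drop = FALSE]
      q_new <- s$weights[r]
    }
    if (s$kind == "label" && off_rotamer && length(s$dihedral_quads)) {
      # perturb the label's mobile dihedrals in place
      co_tmp <- co
      co_tmp[s$atoms, ] <- new_res_co
      for (q in s$dihedral_quads) {
        cur <- measure_dihedral(co_tmp[q[1], ], co_tmp[q[2], ],
                                co_tmp[q[3], ], co_tmp[q[4], ])
        # downstream within the residue: atoms after the third quad atom in
        # the label's own connectivity; approximate by all side-chain atoms
        # farther along the arm
        ds <- s$atoms[seq(match(q[4], s$atoms), length(s$atoms))]
        co_tmp <- set_dihedral(co_tmp, q, ds,
                               wrap_angle(cur + stats::rnorm(1, 0, off_sigma)))
      }
      new_res_co <- co_tmp[s$atoms, , drop = FALSE]
    }
    sc_new <- new_res_co[match(s$sidechain, s$atoms), , drop = FALSE]
    e_old <- site_energy(s, co, co[s$sidechain, , drop = FALSE])
    co_new <- co
    co_new[s$atoms, ] <- new_res_co
    e_new <- site_energy(s, co_new, sc_new)
    dE <- e_new - e_old
    log_acc <- if (is.infinite(kT) && kT > 0) 0
      else -dE / kT
    if (proposal_correction && !is.na(s$cur_rot) && !is.infinite(kT)) {
      q_old <- s$weights[s$cur_rot]
      log_acc <- log_acc + log(q_old) - log(q_new)
    }
    if (is.nan(log_acc)) log_acc <- 0  # dE = 0 at kT = 0
    if (log_acc >= 0 || log(stats::runif(1)) < log_acc) {
      co <- co_new
      e_rel <- e_rel + dE
      sites[[si]]$cur_rot <- r
      accepted[step] <- TRUE
      if (store_frames) frames[[length(frames) + 1]] <- co
    }
    energies[step] <- e_rel
    states[step, ] <- vapply(sites, function(x) x$cur_rot, 1L)
  }

  structure(list(frames = frames, energies = energies, accepted = accepted,
                 states = states,
                 region = do.call(rbind, lapply(sites, function(s)
                   data.frame(chain = s$chain, resnum = s$resnum,
                              resname = s$resname, kind = s$kind,
                              stringsAsFactors = FALSE))),
                 structure = work, labels = labels, seed = seed, kT = kT),
            class = "RepackTrajectory")
}

#' @export
print.RepackTrajectory <- function(x, ...) {
  cat(sprintf("<RepackTrajectory: %d steps, %d accepted, %d region site(s)>\n",
              length(x$energies), sum(x$accepted), nrow(x$region)))
  invisible(x)
}

#' Build a SpinLabel from a repacking trajectory
#'
#' Collects the labeled site's conformations from the post-burn-in accepted
#' frames, merges frames whose mobile dihedrals agree within 1e-6 degrees,
#' and weights each unique rotamer by its frame fraction.
#'
#' @param traj a `RepackTrajectory`.
#' @param site list(chain, resnum) identifying which label to extract.
#' @param burn_in number of initial frames to discard (0 <= burn_in <
#'   frame count); default 20% of the frames.
#' @return a `SpinLabel`.
#' @export
from_trajectory <- function(traj, site,
                            burn_in = floor(0.2 * length(traj$frames))) {
  nf <- length(traj$frames)
  if (burn_in < 0 || burn_in >= nf)
    stop("burn_in must be in [0, frame count)", call. = FALSE)
  keys <- vapply(traj$labels, function(l) paste(l$site$chain, l$site$resnum), "")
  li <- match(paste(site$chain, site$resnum), keys)
  if (is.na(li)) stop("site is not a labeled site of this trajectory",
                      call. = FALSE)
  lab <- traj$labels[[li]]
  a <- traj$structure$atoms
  res <- residue_indices(traj$structure, site$chain, site$resnum)
  idx <- res[match(lab$atom_names, a$name[res])]
  use <- traj$frames[(burn_in + 1):nf]
  quads <- lapply(lab$dihedral_defs, function(q) idx[match(q, lab$atom_names)])
  dihs <- t(vapply(use, function(fr)
    vapply(quads, function(q)
      measure_dihedral(fr[q[1], ], fr[q[2], ], fr[q[3], ], fr[q[4], ]), 0),
    numeric(length(quads))))
  if (!length(quads)) dihs <- matrix(0, length(use), 0)
  if (is.null(dim(dihs))) dihs <- matrix(dihs, ncol = max(1, length(quads)))
  key <- apply(round(dihs / 1e-6) * 1e-6, 1, paste, collapse = "|")
  uk <- unique(key)
  n_rot <- length(uk)
  coords <- array(0, c(n_rot, length(idx), 3))
  weights <- numeric(n_rot)
  dmat <- matrix(0, n_rot, length(quads))
  for (u in seq_along(uk)) {
    w <- which(key == uk[u])
    coords[u, , ] <- use[[w[1]]][idx, ]
    weights[u] <- length(w) / length(use)
    if (length(quads)) dmat[u, ] <- dihs[w[1], ]
  }
  lib_stub <- list(name = paste0(lab$library, "-repacked"),
                   resname = lab$resname, atom_names = lab$atom_names,
                   elements = lab$elements, spin_atoms = lab$spin_atoms,
                   spin_weights = lab$spin_weights, spin_idx = lab$spin_idx,
                   dihedral_defs = lab$dihedral_defs)
  new_spin_label(lib_stub, site, coords, weights, dmat,
                 provenance = list(method = "trajectory", burn_in = burn_in,
                                   frames = length(use)))
}
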