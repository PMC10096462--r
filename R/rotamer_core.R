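# RotamerEnsemble / SpinLabel: a rotamer library instantiated at a protein
# site. Three construction modes mirror the standard label-modeling methods:
# the rotamer-library (RL) method (sample = NULL), off-rotamer sampling
# (sample = n with finite sigmas), and the accessible-volume (AV) method
# (sample = n with dihedral_sigmas = Inf, i.e. uniform dihedral sampling).

new_spin_label <- function(library, site, coords, weights, dihedrals,
                           provenance) {
  w <- weights / sum(weights)
  structure(list(
    library = library$name, resname = library$resname,
    atom_names = library$atom_names, elements = library$elements,
    site = site, coords = coords, weights = w, dihedrals = dihedrals,
    spin_atoms = library$spin_atoms, spin_weights = library$spin_weights,
    spin_idx = library$spin_idx, dihedral_defs = library$dihedral_defs,
    provenance = provenance),
    class = c("SpinLabel", "RotamerEnsemble"))
}

#' @export
print.SpinLabel <- function(x, ...) {
  cat(sprintf("<SpinLabel %s at %s%d: %d rotamers (method '%s')>\n",
              x$library, x$site$chain, x$site$resnum, length(x$weights),
              x$provenance$method))
  invisible(x)
}

#' Draw off-rotamer dihedral samples from a library
#'
#' Each sample picks a parent rotamer with probability equal to its library
#' weight, then perturbs every mobile dihedral by a wrapped normal of the
#' given sigma. Sigma = Inf gives uniform sampling on (-180, 180] (the
#' accessible-volume limit); sigma = 0 reproduces the parent exactly.
#' Sample weights are uniform (1/n): the proposal equals the target mixture,
#' and clash reweighting happens downstream.
#'
#' @param library a `RotamerLibrary`.
#' @param n number of samples (>= 1).
#' @param dihedral_sigmas per-dihedral sigma override in degrees (scalar or
#'   vector); NULL uses the library's sigmas, or 35 degrees if it has none.
#' @param seed RNG seed for reproducibility (NULL for ambient RNG state).
#' @return list with `dihedrals` (n x k), `parents` (n), `weights` (n, = 1/n).
#' @export
sample_off_rotamers <- function(library, n, dihedral_sigmas = NULL,
                                seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  k <- length(library$dihedral_quads)
  sig <- resolve_sigmas(library, dihedral_sigmas)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  parents <- sample.int(nrow(library$dihedrals), n, replace = TRUE,
                        prob = library$weights)
  dih <- library$dihedrals[parents, , drop = FALSE]
  if (k > 0) {
    for (j in seq_len(k)) {
      s <- if (is.matrix(sig)) sig[parents, j] else rep(sig[j], n)
      if (any(s < 0)) stop("dihedral_sigmas must be >= 0", call. = FALSE)
      inf <- is.infinite(s)
      out <- numeric(n)
      if (any(inf)) out[inf] <- stats::runif(sum(inf), -180, 180)
      if (any(!inf))
        out[!inf] <- dih[!inf, j] + stats::rnorm(sum(!inf), 0, s[!inf])
      dih[, j] <- wrap_angle(out)
    }
  }
  list(dihedrals = dih, parents = parents, weights = rep(1 / n, n))
}

resolve_sigmas <- function(library, dihedral_sigmas) {
  k <- length(library$dihedral_quads)
  if (!is.null(dihedral_sigmas)) {
    s <- dihedral_sigmas
    if (length(s) == 1) s <- rep(s, k)
    if (!is.matrix(s) && length(s) != k)
      stop("dihedral_sigmas must have one value per mobile dihedral",
           call. = FALSE)
    return(s)
  }
  if (!is.null(library$dihedral_sigmas)) return(library$dihedral_sigmas)
  rep(35, k)  # default breadth when the library does not specify
}

# Rebuild a rotamer's coordinates with new mobile dihedral values: take the
# parent conformer (preserving its stereochemistry) and rotate each mobile
# dihedral into place, proximal to distal.
coords_with_dihedrals <- function(library, parent, values) {
  co <- library$coords[parent, , , drop = TRUE]
  for (k in seq_along(library$dihedral_quads))
    co <- set_dihedral(co, library$dihedral_quads[[k]],
                       library$downstream[[k]], values[k])
  co
}

#' Attach a rotamer library to a protein site
#'
#' Aligns the library's rotamers (or off-rotamer samples) onto the site
#' backbone, optionally evaluates clashes against the environment, then
#' Boltzmann-reweights and trims the ensemble.
#'
#' The clash environment defaults to the whole protein minus the labeled
#' residue's own side chain; waters are always excluded. Pass `env_subset`
#' to restrict it further (ligands etc. are environment unless you exclude
#' them).
#'
#' @param library a `RotamerLibrary`.
#' @param protein a `StructureModel`.
#' @param chain,resnum labeling site (author numbering from the PDB).
#' @param sample NULL for the plain rotamer-library method, or an integer n
#'   for n off-rotamer samples (with `dihedral_sigmas = Inf` this is the
#'   accessible-volume method).
#' @param dihedral_sigmas off-rotamer sigma override (degrees; Inf allowed).
#' @param alignment "bisect" (default) or "triad" (least-squares on N/CA/C).
#' @param eval_clash evaluate and reweight clashes (default TRUE).
#' @param energy_func energy function (ensemble, environment, params) ->
#'   per-rotamer kcal/mol; default [flat_top_repulsive_lj()].
#' @param params an `lj_params` object (forgive, cap, cutoff, kT, trim_tol).
#' @param env_subset optional `AtomSubset` restricting the environment.
#' @param seed RNG seed for off-rotamer sampling.
#' @return a `SpinLabel`.
#' @export
attach_label <- function(library, protein, chain, resnum, sample = NULL,
                         dihedral_sigmas = NULL,
                         alignment = c("bisect", "triad"), eval_clash = TRUE,
                         energy_func = flat_top_repulsive_lj,
                         params = lj_params(), env_subset = NULL,
                         seed = NULL) {
  alignment <- match.arg(alignment)
  bb <- backbone_indices(protein, chain, resnum)
  site_co <- protein$coords[[1]][bb, , drop = FALSE]

  if (is.null(sample)) {
    n_rot <- nrow(library$dihedrals)
    coords <- library$coords
    weights <- library$weights
    dihedrals <- library$dihedrals
    method <- "rotlib"
  } else {
    sm <- sample_off_rotamers(library, sample, dihedral_sigmas, seed)
    n_rot <- sample
    coords <- array(0, c(n_rot, length(library$atom_names), 3))
    for (r in seq_len(n_rot))
      coords[r, , ] <- coords_with_dihedrals(library, sm$parents[r],
                                             sm$dihedrals[r, ])
    weights <- sm$weights
    dihedrals <- sm$dihedrals
    method <- "sample"
  }

  iN <- match("N", library$atom_names); iCA <- match("CA", library$atom_names)
  iC <- match("C", library$atom_names)
  superpose <- if (alignment == "bisect") bisect_superposition else triad_superposition
  for (r in seq_len(n_rot)) {
    co <- coords[r, , , drop = TRUE]
    tf <- superpose(co[iN, ], co[iCA, ], co[iC, ],
                    site_co[1, ], site_co[2, ], site_co[3, ])
    coords[r, , ] <- apply_transform(tf, co)
  }

  prov <- list(method = method, alignment = alignment,
               eval_clash = eval_clash, sample = sample,
               dihedral_sigmas = if (is.null(sample)) NULL else
                 resolve_sigmas(library, dihedral_sigmas),
               seed = seed,
               params = params[c("forgive", "cap", "cutoff", "kT", "trim_tol")])
  label <- new_spin_label(library, list(chain = chain, resnum = resnum),
                          coords, weights, dihedrals, prov)

  if (eval_clash) {
    env <- clash_environment(protein, chain, resnum, env_subset)
    energies <- energy_func(label, env, params)
    if (length(energies) != n_rot || !all(is.finite(energies)))
      stop("energy function must return one finite energy per rotamer",
           call. = FALSE)
    post <- try(reweight(label$weights, energies, params$kT), silent = TRUE)
    if (inherits(post, "try-error"))
      stop("empty ensemble: all rotamers clash; increase forgive or cap",
           call. = FALSE)
    tr <- trim_weights(post, params$trim_tol)
    label$coords <- label$coords[tr$keep, , , drop = FALSE]
    label$weights <- tr$weights
    label$dihedrals <- label$dihedrals[tr$keep, , drop = FALSE]
    label$provenance$energies <- energies[tr$keep]
  }
  label
}

# Environment = provided subset (default: everything) minus the labeled
# residue, minus waters. The whole residue is excluded -- not just its side
# chain -- because the grafted side chain is covalently bonded to the site
# backbone and its 1-2/1-3 contacts (CB-CA, SG-N, ...) would otherwise
# register as huge spurious clashes.
clash_environment <- function(protein, chain, resnum, env_subset = NULL) {
  idx <- if (is.null(env_subset)) seq_len(n_atoms(protein)) else env_subset$idx
  a <- protein$atoms
  own <- a$chain == chain & a$resnum == resnum
  water <- a$resname %in% c("HOH", "WAT")
  new_atom_subset(protein, setdiff(idx, which(own | water)))
}
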