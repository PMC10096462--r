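# Clash scoring and ensemble reweighting.
#
# The default score is a purely repulsive 12-power Lennard-Jones with a
# forgive factor f scaling the contact radius and a hard per-pair cap:
#
#   E = sum over pairs (i in label side chain, j in environment, r_ij <= cutoff)
#         min(E_cap, eps_ij * ((f * rmin_ij) / r_ij)^12)
#
# with rmin_ij = rmin_i/2 + rmin_j/2 and eps_ij = sqrt(eps_i * eps_j).
# The attractive 6-term is omitted by default because it biases rotamers
# toward the protein surface when solvent is absent; lj_energy_12_6 provides
# the full potential for comparison.

# Element-keyed Lennard-Jones parameters: rmin/2 in Angstrom, epsilon in
# kcal/mol. Literature-typical values; swappable via lj_params(table = ...).
default_lj_table <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "S", "P", "Br", "Cu", "Gd"),
    rmin2 = c(1.10, 1.90, 1.85, 1.70, 2.00, 2.10, 2.20, 1.40, 1.80),
    eps = c(0.016, 0.070, 0.160, 0.120, 0.450, 0.585, 0.320, 0.050, 0.100),
    stringsAsFactors = FALSE)
}

#' Energy-function parameters
#'
#' Defaults: forgive 0.9, cap 10 kcal/mol, cutoff 10 A, kT 0.593 kcal/mol
#' (298 K), trim tolerance 0.005. All recorded in ensemble provenance.
#'
#' @param forgive forgive factor in (0, 1.2], scales the contact radius.
#' @param cap per-pair maximum energy (kcal/mol), the "flat top".
#' @param cutoff pair-distance cutoff for clash evaluation (Angstrom).
#' @param kT Boltzmann factor (kcal/mol).
#' @param trim_tol cumulative weight discarded when trimming.
#' @param table element-keyed data frame with columns element, rmin2, eps.
#' @param sasa_probe,sasa_n_points Shrake-Rupley probe radius and sphere points.
#' @return a list of class `lj_params`.
#' @export
lj_params <- function(forgive = 0.9, cap = 10, cutoff = 10, kT = 0.593,
                      trim_tol = 0.005, table = default_lj_table(),
                      sasa_probe = 1.4, sasa_n_points = 256) {
  stopifnot(forgive > 0, forgive <= 1.2, cap > 0, cutoff > 0, kT > 0,
            trim_tol >= 0, trim_tol < 1)
  structure(list(forgive = forgive, cap = cap, cutoff = cutoff, kT = kT,
                 trim_tol = trim_tol, table = table, sasa_probe = sasa_probe,
                 sasa_n_points = sasa_n_points), class = "lj_params")
}

lj_lookup <- function(elements, table) {
  i <- match(elements, table$element)
  if (anyNA(i))
    stop("unknown element in LJ table: ",
         paste(unique(elements[is.na(i)]), collapse = ","), call. = FALSE)
  list(rmin2 = table$rmin2[i], eps = table$eps[i])
}

sidechain_atom_idx <- function(ensemble)
  which(!(ensemble$atom_names %in% c("N", "CA", "C", "O")))

env_coords_elements <- function(environment) {
  s <- environment$structure
  i <- environment$idx
  keep <- !(s$atoms$resname[i] %in% c("HOH", "WAT"))
  list(coords = s$coords[[1]][i[keep], , drop = FALSE],
       elements = s$atoms$element[i[keep]])
}

# Pairwise clash energy between one coordinate set and an environment.
pair_lj_energy <- function(coords, elements, env_co, env_el, params,
                           repulsive_only = TRUE) {
  if (!nrow(coords) || !nrow(env_co)) return(0)
  p1 <- lj_lookup(elements, params$table)
  p2 <- lj_lookup(env_el, params$table)
  d2 <- outer(rowSums(coords^2), rowSums(env_co^2), `+`) -
    2 * coords %*% t(env_co)
  d <- sqrt(pmax(d2, 1e-12))
  rmin <- outer(p1$rmin2, p2$rmin2, `+`)
  eps <- sqrt(outer(p1$eps, p2$eps))
  within <- d <= params$cutoff
  if (!any(within)) return(0)
  ratio <- (params$forgive * rmin[within] / d[within])^2
  e <- eps[within] * ratio^6
  if (!repulsive_only) e <- e - 2 * eps[within] * ratio^3
  sum(pmin(params$cap, e))
}

rotamer_energies <- function(ensemble, environment, params,
                             repulsive_only = TRUE) {
  env <- env_coords_elements(environment)
  sc <- sidechain_atom_idx(ensemble)
  el <- ensemble$elements[sc]
  vapply(seq_len(dim(ensemble$coords)[1]), function(r) {
    co <- ensemble$coords[r, sc, , drop = TRUE]
    if (is.null(dim(co))) co <- matrix(co, ncol = 3)
    pair_lj_energy(co, el, env$coords, env$elements, params, repulsive_only)
  }, 0)
}

#' Flat-top repulsive Lennard-Jones clash score
#'
#' Conforms to the energy-function contract: takes an ensemble and an
#' environment `AtomSubset` and returns one energy per rotamer (kcal/mol).
#' Zero when no label-environment pair is within the cutoff; each pair's
#' energy is capped at `params$cap`. Waters in the environment are ignored.
#'
#' @param ensemble a `RotamerEnsemble`/`SpinLabel`.
#' @param environment an `AtomSubset` (must exclude the ensemble's own atoms).
#' @param params an `lj_params` object.
#' @return numeric vector, one energy per rotamer.
#' @export
flat_top_repulsive_lj <- function(ensemble, environment, params = lj_params())
  rotamer_energies(ensemble, environment, params, repulsive_only = TRUE)

#' Full 12-6 Lennard-Jones variant (capped, forgive-scaled)
#'
#' Provided for comparison with the default repulsive-only score.
#' @inheritParams flat_top_repulsive_lj
#' @return numeric vector, one energy per rotamer.
#' @export
lj_energy_12_6 <- function(ensemble, environment, params = lj_params())
  rotamer_energies(ensemble, environment, params, repulsive_only = FALSE)

#' Boltzmann reweighting of rotamer weights
#'
#' Posterior w_i is proportional to prior_i * exp(-E_i / kT); invariant to
#' adding a constant to all energies.
#'
#' @param prior_weights nonnegative prior weights.
#' @param energies energies in kcal/mol, same length.
#' @param kT Boltzmann factor in kcal/mol.
#' @return posterior weights summing to 1.
#' @export
reweight <- function(prior_weights, energies, kT) {
  stopifnot(length(prior_weights) == length(energies), kT > 0)
  w <- prior_weights * exp(-(energies - min(energies)) / kT)
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("degenerate weights: all posterior mass underflows", call. = FALSE)
  w / s
}

#' Trim low-population rotamers
#'
#' Keeps the smallest prefix of weight-sorted rotamers whose cumulative
#' weight reaches 1 - trim_tol, then renormalizes. At least one rotamer
#' always survives and relative weights among survivors are preserved.
#'
#' @param weights rotamer weights (sum 1).
#' @param trim_tol cumulative weight allowed to be discarded, in [0, 1).
#' @return list with `keep` (indices into the input, ascending) and
#'   `weights` (renormalized survivor weights).
#' @export
trim_weights <- function(weights, trim_tol) {
  stopifnot(trim_tol >= 0, trim_tol < 1)
  o <- order(weights, decreasing = TRUE)
  cum <- cumsum(weights[o])
  k <- which(cum >= 1 - trim_tol - 1e-12)[1]
  if (is.na(k)) k <- length(weights)
  keep <- sort(o[seq_len(k)])
  list(keep = keep, weights = weights[keep] / sum(weights[keep]))
}

# Deterministic quasi-uniform sphere points (golden-spiral / Fibonacci).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the sphere-point method: the fraction of `n_points`
#' points on the probe-expanded sphere not buried inside any neighbor's
#' expanded sphere, times the expanded sphere's area.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom radii (Angstrom).
#' @param probe probe radius (Angstrom), default 1.4 (water).
#' @param n_points sphere points per atom (>= 16).
#' @return per-atom areas in square Angstrom.
#' @export
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, n_points = 256) {
  stopifnot(probe >= 0, n_points >= 16, nrow(coords) == length(radii))
  n <- nrow(coords)
  R <- radii + probe
  pts <- sphere_points(n_points)
  d2 <- outer(rowSums(coords^2), rowSums(coords^2), `+`) -
    2 * coords %*% t(coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, coords[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
          (p[, 3] - coords[j, 3])^2
        free <- free & dj > R[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    out[i] <- frac * 4 * pi * R[i]^2
  }
  out
}

sasa_radii <- function(elements, table = default_lj_table())
  lj_lookup(elements, table)$rmin2

#' SASA-augmented clash score
#'
#' The flat-top repulsive Lennard-Jones score augmented with an attractive
#' term proportional to the rotamer's solvent-accessible surface area,
#' capturing van der Waals contacts with the (implicit) solvent that the
#' repulsive score ignores: E_i = LJ_i - w_sasa * SASA_i, where SASA_i is
#' the summed side-chain SASA of rotamer i in the context of the environment.
#'
#' @inheritParams flat_top_repulsive_lj
#' @param w_sasa nonnegative weight (kcal/mol per square Angstrom).
#' @return numeric vector, one energy per rotamer.
#' @export
sasa_augmented_energy <- function(ensemble, environment, params = lj_params(),
                                  w_sasa = 0.01) {
  stopifnot(w_sasa >= 0)
  elj <- flat_top_repulsive_lj(ensemble, environment, params)
  if (w_sasa == 0) return(elj)
  env <- env_coords_elements(environment)
  sc <- sidechain_atom_idx(ensemble)
  el <- ensemble$elements[sc]
  sasa <- vapply(seq_len(dim(ensemble$coords)[1]), function(r) {
    co <- ensemble$coords[r, sc, , drop = TRUE]
    if (is.null(dim(co))) co <- matrix(co, ncol = 3)
    # restrict context to nearby environment atoms for speed
    ctr <- colMeans(co)
    d2 <- rowSums(sweep(env$coords, 2, ctr)^2)
    near <- d2 < (params$cutoff + 8)^2
    allco <- rbind(co, env$coords[near, , drop = FALSE])
    rad <- sasa_radii(c(el, env$elements[near]), params$table)
    a <- shrake_rupley_sasa(allco, rad, params$sasa_probe, params$sasa_n_points)
    sum(a[seq_len(nrow(co))])
  }, 0)
  elj - w_sasa * sasa
}
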