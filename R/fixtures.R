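# Synthetic test inputs: ideal poly-alanine helices, a toy nitroxide-like
# label library, a two-conformation hinge protein, and synthetic membrane
# depth datasets. These validate code paths, not chemistry: geometries are
# idealized and the toy label is a minimal 5-atom arm whose spin centers sit
# 4-8 A from CA, comparable to a real nitroxide side chain.

# Ideal backbone internal coordinates (Angstrom / degrees).
BB_GEOM <- list(b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
                b_CACB = 1.521,
                a_NCAC = 111.0, a_CACN = 116.2, a_CNCA = 121.7,
                a_CACO = 120.5, a_NCACB = 110.4)

#' Generate an ideal poly-alanine alpha-helix
#'
#' phi = -57, psi = -47, omega = 180, standard bond geometry; full backbone
#' plus CB and O. The helix axis is aligned with z (rise about 1.5 A per
#' residue). Deterministic.
#'
#' @param n_res number of residues (>= 3).
#' @param chain chain identifier.
#' @return a `StructureModel`.
#' @export
make_helix <- function(n_res, chain = "A") {
  if (n_res < 3) stop("n_res must be >= 3", call. = FALSE)
  g <- BB_GEOM
  phi <- -57; psi <- -47; omega <- 180
  # backbone chain N-CA-C repeated, then O and CB per residue
  bb <- matrix(NA_real_, n_res * 3, 3)
  bb[1, ] <- c(0, 0, 0)
  bb[2, ] <- c(g$b_NCA, 0, 0)
  bb[3, ] <- as.numeric(nerf_place(c(-1, 1, 0), bb[1, ], bb[2, ],
                                   g$b_CAC, g$a_NCAC, -120))
  for (i in 4:(n_res * 3)) {
    kind <- i %% 3  # 1 = N, 2 = CA, 0 = C
    prev <- bb[(i - 3):(i - 1), , drop = FALSE]
    par <- switch(as.character(kind),
                  "1" = c(g$b_CN, g$a_CACN, psi),
                  "2" = c(g$b_NCA, g$a_CNCA, omega),
                  "0" = c(g$b_CAC, g$a_NCAC, phi))
    bb[i, ] <- as.numeric(nerf_place(prev[1, ], prev[2, ], prev[3, ],
                                     par[1], par[2], par[3]))
  }
  atoms <- list(); coords <- list()
  serial <- 0L
  for (r in seq_len(n_res)) {
    iN <- (r - 1) * 3 + 1; iCA <- iN + 1; iC <- iN + 2
    N <- bb[iN, ]; CA <- bb[iCA, ]; C <- bb[iC, ]
    # carbonyl O in the peptide plane: trans to the next N (or to CA-N)
    O <- if (r < n_res)
      as.numeric(nerf_place(bb[iN + 3, ], CA, C, g$b_CO, g$a_CACO, 180))
    else as.numeric(nerf_place(N, CA, C, g$b_CO, g$a_CACO, psi + 180))
    CB <- as.numeric(nerf_place(C, N, CA, g$b_CACB, g$a_NCACB, 122.5))
    nm <- c("N", "CA", "C", "O", "CB")
    el <- c("N", "C", "C", "O", "C")
    for (k in 1:5) {
      serial <- serial + 1L
      atoms[[serial]] <- data.frame(serial = serial, name = nm[k],
                                    element = el[k], resname = "ALA",
                                    resnum = r, chain = chain, occ = 1, b = 0,
                                    stringsAsFactors = FALSE)
    }
    coords[[r]] <- rbind(N, CA, C, O, CB)
  }
  co <- do.call(rbind, coords)
  # align the helix axis (principal axis of the CA trace) with +z
  ca <- co[seq(2, nrow(co), by = 5), , drop = FALSE]
  cen <- colMeans(ca)
  ax <- svd(sweep(ca, 2, cen))$v[, 1]
  if (ax[3] < 0) ax <- -ax
  v <- cross3(ax, c(0, 0, 1))
  if (vnorm(v) > 1e-9) {
    R <- rotation_about_axis(v, acos(max(-1, min(1, ax[3]))))
    co <- sweep(sweep(co, 2, cen) %*% t(R), 2, cen, `+`)
  }
  ca_z <- co[seq(2, nrow(co), by = 5), 3]
  if (ca_z[length(ca_z)] < ca_z[1]) {  # residue 1 at the bottom
    R <- rotation_about_axis(c(1, 0, 0), pi)
    co <- sweep(sweep(co, 2, cen) %*% t(R), 2, cen, `+`)
  }
  rownames(co) <- NULL
  new_structure_model(do.call(rbind, atoms), list(co),
                      sprintf("helix%d", n_res))
}

#' Build the toy nitroxide-like label library
#'
#' A 3-rotamer library named "TOY" (residue "TYL") with a CB-SG-C1-N1-O1 arm,
#' two mobile dihedrals (N-CA-CB-SG and CA-CB-SG-C1), weights (0.5, 0.3,
#' 0.2) and spin atoms N1/O1 with equal spin weights. Deterministic; passes
#' [validate_library()] cleanly. Stands in for a real nitroxide label in all
#' tests.
#'
#' @return a `RotamerLibrary`.
#' @export
make_toy_label_library <- function() {
  g <- BB_GEOM
  names_ <- c("N", "CA", "C", "O", "CB", "SG", "C1", "N1", "O1")
  elems <- c("N", "C", "C", "O", "C", "S", "C", "N", "O")
  build_rot <- function(chi1, chi2) {
    co <- matrix(NA_real_, 9, 3)
    a <- g$a_NCAC * pi / 180
    co[2, ] <- c(0, 0, 0)                                   # CA
    co[1, ] <- c(g$b_NCA * cos(a / 2), g$b_NCA * sin(a / 2), 0)   # N
    co[3, ] <- c(g$b_CAC * cos(a / 2), -g$b_CAC * sin(a / 2), 0)  # C
    co[4, ] <- as.numeric(nerf_place(co[1, ], co[2, ], co[3, ], g$b_CO,
                                     g$a_CACO, -45))        # O (arbitrary fixed)
    co[5, ] <- as.numeric(nerf_place(co[3, ], co[1, ], co[2, ], g$b_CACB,
                                     g$a_NCACB, 122.5))     # CB (improper)
    co[6, ] <- as.numeric(nerf_place(co[1, ], co[2, ], co[5, ], 1.81, 114,
                                     chi1))                 # SG
    co[7, ] <- as.numeric(nerf_place(co[2, ], co[5, ], co[6, ], 1.80, 100,
                                     chi2))                 # C1
    co[8, ] <- as.numeric(nerf_place(co[5, ], co[6, ], co[7, ], 1.40, 120,
                                     180))                  # N1
    co[9, ] <- as.numeric(nerf_place(co[6, ], co[7, ], co[8, ], 1.28, 125,
                                     180))                  # O1
    co
  }
  chis <- rbind(c(-60, -60), c(180, 60), c(60, 180))
  coords <- array(0, c(3, 9, 3))
  for (r in 1:3) coords[r, , ] <- build_rot(chis[r, 1], chis[r, 2])
  new_rotamer_library(
    name = "TOY", resname = "TYL", atom_names = names_, elements = elems,
    coords = coords,
    dihedral_defs = list(c("N", "CA", "CB", "SG"), c("CA", "CB", "SG", "C1")),
    spin_atoms = c("N1", "O1"), spin_weights = c(0.5, 0.5),
    weights = c(0.5, 0.3, 0.2), dihedral_sigmas = c(25, 25))
}

#' Generate a two-conformation hinge protein
#'
#' Two helical arms sharing residue numbering; in state B the second arm is
#' rotated by `hinge_angle` about an axis through the spin centroid of the
#' label attached (clash-free) at the designated "decoupled" site on arm 2.
#' By construction that site's spin-label distance distributions barely
#' change between states while its CB moves substantially -- the analogue of
#' a site pair with large backbone change but little distance-distribution
#' contrast.
#'
#' @param n_res total residues (>= 8, even recommended).
#' @param hinge_angle rotation of arm 2 in degrees, in (0, 180).
#' @return list with `a`, `b` (StructureModels), `hinge_res` (first residue
#'   of arm 2) and `decoupled_res` (the constructed low-contrast site).
#' @export
make_hinge <- function(n_res = 16, hinge_angle = 70) {
  if (n_res < 8) stop("n_res must be >= 8", call. = FALSE)
  if (hinge_angle < 0 || hinge_angle >= 180)
    stop("hinge_angle must be in [0, 180)", call. = FALSE)
  s <- make_helix(n_res)
  half <- n_res %/% 2
  decoupled <- half + 2
  lib <- make_toy_label_library()
  # clash-evaluated, as pair_screen attaches: the pivot must match the
  # centroid of the ensemble the screen will actually see
  lab <- attach_label(lib, s, "A", decoupled)
  pivot <- spin_centroid(lab)
  axis <- c(1, 0, 0)  # perpendicular to the z-aligned helix axis
  arm2 <- which(s$atoms$resnum > half)
  co <- s$coords[[1]]
  R <- rotation_about_axis(axis, hinge_angle * pi / 180)
  co2 <- co
  co2[arm2, ] <- sweep(sweep(co[arm2, , drop = FALSE], 2, pivot) %*% t(R),
                       2, pivot, `+`)
  b <- new_structure_model(s$atoms, list(co2), sprintf("hingeB%d", n_res))
  list(a = s, b = b, hinge_res = half + 1, decoupled_res = decoupled)
}

#' Generate a synthetic membrane-depth dataset
#'
#' Attaches the toy label at each site, applies `true_pose`, and records the
#' transformed spin-centroid z (plus optional Gaussian noise) as the
#' measured depth.
#'
#' @param structure a `StructureModel`.
#' @param sites data frame with columns chain, resnum.
#' @param true_pose a pose list (z, alpha, beta, gamma) as for
#'   [fit_membrane_pose()]; NULL for the identity pose.
#' @param noise_sigma depth noise standard deviation (Angstrom).
#' @param seed RNG seed.
#' @param library rotamer library for the labels (default toy label).
#' @param eval_clash passed to [attach_label()].
#' @return list with `dataset` (chain, resnum, depth, sigma) and `centroids`
#'   (site x 3 matrix of untransformed spin centroids).
#' @export
make_depths <- function(structure, sites, true_pose = NULL, noise_sigma = 0,
                        seed = NULL, library = make_toy_label_library(),
                        eval_clash = TRUE) {
  cents <- matrix(0, nrow(sites), 3)
  for (k in seq_len(nrow(sites))) {
    lab <- attach_label(library, structure, sites$chain[k], sites$resnum[k],
                        eval_clash = eval_clash)
    cents[k, ] <- spin_centroid(lab)
  }
  z <- if (is.null(true_pose)) cents[, 3] else {
    tf <- pose_transform(true_pose, center = colMeans(cents))
    apply_transform(tf, cents)[, 3]
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    z <- z + stats::rnorm(length(z), 0, noise_sigma)
  }
  list(dataset = data.frame(chain = sites$chain, resnum = sites$resnum,
                            depth = z, sigma = noise_sigma,
                            stringsAsFactors = FALSE),
       centroids = cents)
}
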