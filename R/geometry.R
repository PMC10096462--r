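# Vector and rigid-body geometry primitives shared by all modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles (degrees) into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

#' Measure a signed torsion angle
#'
#' Standard IUPAC sign convention: looking down the p2 -> p3 axis, a
#' positive angle corresponds to a clockwise rotation of p4 relative to p1.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (coordinates in Angstrom).
#' @return angle in degrees in (-180, 180].
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate geometry: collinear atoms in dihedral", call. = FALSE)
  b2u <- b2 / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# Rodrigues rotation matrix for rotation by theta (radians) about unit axis k.
rotation_about_axis <- function(k, theta) {
  k <- unit(k)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Set a mobile dihedral angle by rigid rotation of downstream atoms
#'
#' Bond lengths and bond angles are left untouched: only the atoms listed in
#' `downstream` rotate rigidly about the p2-p3 bond axis.
#'
#' @param coords n x 3 coordinate matrix.
#' @param quad integer vector of length 4: row indices of the dihedral atoms.
#' @param downstream integer row indices rotated with the dihedral (must not
#'   include the first three atoms of `quad`).
#' @param value target dihedral in degrees.
#' @return updated coordinate matrix.
#' @export
set_dihedral <- function(coords, quad, downstream, value) {
  cur <- measure_dihedral(coords[quad[1], ], coords[quad[2], ],
                          coords[quad[3], ], coords[quad[4], ])
  delta <- (value - cur) * pi / 180
  if (abs(delta) < 1e-15) return(coords)
  axis <- coords[quad[3], ] - coords[quad[2], ]
  R <- rotation_about_axis(axis, delta)
  origin <- coords[quad[2], ]
  sub <- coords[downstream, , drop = FALSE]
  sub <- sweep(sub, 2, origin)
  sub <- sub %*% t(R)
  coords[downstream, ] <- sweep(sub, 2, origin, `+`)
  coords
}

# Orthonormal frame of a backbone triad: columns are (bisector of N-CA-C,
# in-plane perpendicular, plane normal), origin at CA.
triad_frame <- function(N, CA, C) {
  v1 <- N - CA; v2 <- C - CA
  if (vnorm(v1) < 1e-8 || vnorm(v2) < 1e-8)
    stop("degenerate geometry: coincident triad atoms", call. = FALSE)
  u1 <- unit(v1); u2 <- unit(v2)
  s <- u1 + u2
  if (vnorm(s) < 1e-8 || vnorm(cross3(u1, u2)) < 1e-8)
    stop("degenerate geometry: triad angle at CA is 0 or 180 degrees",
         call. = FALSE)
  e1 <- unit(s)                 # bisector
  e3 <- unit(cross3(u1, u2))    # plane normal
  e2 <- cross3(e3, e1)
  cbind(e1, e2, e3)
}

new_rigid_transform <- function(R, t) {
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#' @param tf a `RigidTransform`.
#' @param coords n x 3 matrix or length-3 vector.
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(tf, coords) {
  if (is.null(dim(coords))) return(as.numeric(tf$R %*% coords + tf$t))
  sweep(coords %*% t(tf$R), 2, tf$t, `+`)
}

compose_transform <- function(a, b) {
  # (a o b)(x) = a(b(x))
  new_rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Bisector-based backbone superposition
#'
#' Translates so the CA atoms coincide, then rotates so the N-CA-C planes
#' and the vectors bisecting the N-CA-C angles are aligned. Side-chain atoms
#' are thereby not biased to either side of the residue when the two triads
#' have different N-CA-C angles.
#'
#' @param src_N,src_CA,src_C,dst_N,dst_CA,dst_C backbone coordinates.
#' @return a `RigidTransform` mapping the source frame onto the destination.
#' @export
bisect_superposition <- function(src_N, src_CA, src_C, dst_N, dst_CA, dst_C) {
  Fs <- triad_frame(src_N, src_CA, src_C)
  Fd <- triad_frame(dst_N, dst_CA, dst_C)
  R <- Fd %*% t(Fs)
  new_rigid_transform(R, dst_CA - as.numeric(R %*% src_CA))
}

#' Least-squares backbone superposition (Kabsch on N, CA, C)
#'
#' @inheritParams bisect_superposition
#' @return a `RigidTransform` minimizing the RMSD over the three points;
#'   always a proper rotation (det = +1).
#' @export
triad_superposition <- function(src_N, src_CA, src_C, dst_N, dst_CA, dst_C) {
  S <- rbind(src_N, src_CA, src_C)
  D <- rbind(dst_N, dst_CA, dst_C)
  # reuse the triad degeneracy checks
  triad_frame(src_N, src_CA, src_C); triad_frame(dst_N, dst_CA, dst_C)
  cs <- colMeans(S); cd <- colMeans(D)
  H <- t(sweep(S, 2, cs)) %*% sweep(D, 2, cd)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  new_rigid_transform(R, cd - as.numeric(R %*% cs))
}

# Natural extension reference frame: place a new atom given three placed
# reference atoms and internal coordinates (bond Angstrom, angle/dihedral deg).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + cbind(bc, m, n) %*% d2
}
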