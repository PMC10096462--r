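# Rigid-body membrane docking from spin-label depth restraints.
#
# Membrane frame: the phosphate plane is z = 0 and positive z points into
# the hydrocarbon core, so power-saturation depths are used with their
# conventional sign. The pose is a rotation about the centroid of the spin
# centroids (intrinsic Z-Y-Z Euler angles) followed by a z translation.
# Planar depth data cannot constrain the rotation about the membrane
# normal: with R = Rz(alpha) Ry(beta) Rz(gamma), the transformed z depends
# only on beta and gamma, so alpha is reported but flagged unconstrained.

euler_zyz <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

euler_from_matrix <- function(R) {
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-9) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  c(alpha, beta, gamma) * 180 / pi
}

#' Rigid transform of a membrane pose
#'
#' Rotation about `center` by the intrinsic Z-Y-Z Euler angles, then
#' translation by (0, 0, z).
#'
#' @param pose list with z (Angstrom) and alpha, beta, gamma (degrees).
#' @param center rotation center (default origin).
#' @return a `RigidTransform`.
#' @export
pose_transform <- function(pose, center = c(0, 0, 0)) {
  R <- euler_zyz(pose$alpha, pose$beta, pose$gamma)
  t <- center - as.numeric(R %*% center) + c(0, 0, pose$z)
  new_rigid_transform(R, t)
}

#' Depth residuals of a pose
#'
#' residual_i = z(transformed centroid_i) - depth_i, optionally divided by
#' the per-site uncertainty.
#'
#' @param pose pose list (z, alpha, beta, gamma).
#' @param centroids site x 3 matrix of spin centroids.
#' @param dataset data frame with columns depth and optionally sigma.
#' @param center rotation center (default: centroid of `centroids`).
#' @param weighted divide residuals by dataset$sigma where positive.
#' @return numeric residual vector (Angstrom).
#' @export
depth_residuals <- function(pose, centroids, dataset,
                            center = colMeans(centroids), weighted = FALSE) {
  if (nrow(centroids) != nrow(dataset))
    stop("missing site: need one centroid per dataset row", call. = FALSE)
  tf <- pose_transform(pose, center)
  res <- apply_transform(tf, centroids)[, 3] - dataset$depth
  if (weighted && !is.null(dataset$sigma)) {
    s <- ifelse(is.finite(dataset$sigma) & dataset$sigma > 0, dataset$sigma, 1)
    res <- res / s
  }
  res
}

#' Fit a membrane pose to depth data
#'
#' Least-squares fit of (z, alpha, beta, gamma) minimizing the summed
#' squared depth residuals, by Nelder-Mead restarts from dispersed beta
#' starting orientations. alpha (the world-frame rotation about the membrane
#' normal) is not identifiable from planar depths and is flagged accordingly.
#'
#' @param centroids site x 3 matrix of spin centroids.
#' @param dataset data frame with columns depth and optionally sigma.
#' @param init_pose optional starting pose list.
#' @param n_restarts number of starting orientations (default 8).
#' @param seed RNG seed for start jitter (deterministic otherwise).
#' @param weighted use sigma-weighted residuals.
#' @return a `DockingPose`: pose parameters, residuals, ssr and flags.
#' @export
fit_membrane_pose <- function(centroids, dataset, init_pose = NULL,
                              n_restarts = 8, seed = NULL, weighted = FALSE) {
  if (nrow(dataset) < 2)
    stop("under-determined: need at least 2 sites", call. = FALSE)
  if (nrow(dataset) < 4)
    warning("fewer than 4 sites: pose parameters may not all be identifiable")
  center <- colMeans(centroids)
  obj <- function(p) {
    r <- depth_residuals(list(z = p[1], alpha = p[2], beta = p[3],
                              gamma = p[4]), centroids, dataset,
                         center = center, weighted = weighted)
    sum(r^2)
  }
  if (!is.null(seed)) set.seed(seed)
  z0 <- mean(dataset$depth) - center[3]
  starts <- list()
  if (!is.null(init_pose))
    starts[[1]] <- c(init_pose$z, init_pose$alpha, init_pose$beta,
                     init_pose$gamma)
  nb <- max(1, n_restarts - length(starts))
  betas <- seq(0, 180, length.out = nb + 1)[seq_len(nb)]
  alphas <- seq(0, 300, length.out = nb)
  for (k in seq_len(nb))
    starts[[length(starts) + 1]] <- c(z0, alphas[k], betas[k], 0)
  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    # polish: Nelder-Mead restart from its own optimum sharpens convergence
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- best$par
  pose <- list(z = p[1], alpha = wrap_angle(p[2]), beta = wrap_angle(p[3]),
               gamma = wrap_angle(p[4]))
  res <- depth_residuals(pose, centroids, dataset, center = center,
                         weighted = weighted)
  structure(list(z = pose$z, alpha = pose$alpha, beta = pose$beta,
                 gamma = pose$gamma, center = center, residuals = res,
                 ssr = sum(res^2),
                 alpha_unconstrained = TRUE,
                 n_restarts = length(starts)),
            class = "DockingPose")
}

#' @export
print.DockingPose <- function(x, ...) {
  cat(sprintf(paste0("<DockingPose: z = %.2f A, alpha = %.1f, beta = %.1f, ",
                     "gamma = %.1f deg%s; rmsd = %.3f A over %d sites>\n"),
              x$z, x$alpha, x$beta, x$gamma,
              if (x$alpha_unconstrained) " (alpha unconstrained by planar depths)" else "",
              sqrt(x$ssr / length(x$residuals)), length(x$residuals)))
  invisible(x)
}

#' Read a depth table
#'
#' Whitespace-delimited text: `chain resnum depth [sigma]`, `#` comments.
#'
#' @param path file path.
#' @return data frame with chain, resnum, depth, sigma.
#' @export
read_depth_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  out <- do.call(rbind, lapply(parts, function(p) {
    if (length(p) < 3) stop("depth table rows need: chain resnum depth [sigma]",
                            call. = FALSE)
    data.frame(chain = p[1], resnum = as.integer(p[2]),
               depth = as.numeric(p[3]),
               sigma = if (length(p) >= 4) as.numeric(p[4]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(!is.finite(out$depth))) stop("non-finite depth in table", call. = FALSE)
  if (anyDuplicated(paste(out$chain, out$resnum)))
    stop("duplicate sites in depth table", call. = FALSE)
  out
}
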