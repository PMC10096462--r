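# Experimental observables derived from attached spin labels: per-rotamer
# spin centers, ensemble centroids, inter-label distance distributions
# (DEER), the 1-D earth-mover's distance, and solvent-exposure screening of
# candidate labeling sites.

#' Per-rotamer spin centers
#'
#' Row i is the spin_weights-weighted mean of rotamer i's spin-bearing atom
#' coordinates (e.g. the N-O midpoint of a nitroxide).
#'
#' @param label a `SpinLabel`.
#' @return rotamer x 3 matrix (Angstrom).
#' @export
spin_centers <- function(label) {
  if (!length(label$spin_idx)) stop("label has no spin atoms", call. = FALSE)
  sw <- label$spin_weights / sum(label$spin_weights)
  nr <- dim(label$coords)[1]
  out <- matrix(0, nr, 3)
  for (k in seq_along(label$spin_idx))
    out <- out + sw[k] * label$coords[, label$spin_idx[k], , drop = TRUE]
  if (nr == 1) out <- matrix(out, 1, 3)
  out
}

#' Ensemble spin centroid
#'
#' The rotamer-weight-weighted mean of the spin centers: the single point
#' used for aggregate observables such as membrane depth.
#'
#' @param label a `SpinLabel`.
#' @return length-3 numeric vector.
#' @export
spin_centroid <- function(label) {
  sc <- spin_centers(label)
  as.numeric(crossprod(sc, label$weights))
}

#' Heavy-atom centroid of the attached ensemble
#'
#' Rotamer-weight-weighted mean over rotamers of the unweighted mean of each
#' rotamer's heavy (non-hydrogen) atoms.
#'
#' @param label a `SpinLabel` or `RotamerEnsemble`.
#' @return length-3 numeric vector.
#' @export
ensemble_centroid <- function(label) {
  heavy <- which(label$elements != "H")
  nr <- dim(label$coords)[1]
  per <- t(vapply(seq_len(nr), function(r) {
    co <- label$coords[r, heavy, , drop = TRUE]
    if (is.null(dim(co))) co else colMeans(co)
  }, numeric(3)))
  as.numeric(crossprod(per, label$weights))
}

new_distance_distribution <- function(r, P, meta = list()) {
  stopifnot(length(r) == length(P), all(P >= -1e-12), all(diff(r) > 0))
  dr <- r[2] - r[1]
  P <- pmax(P, 0)
  s <- sum(P) * dr
  if (s <= 0) stop("distribution has no mass", call. = FALSE)
  structure(list(r = r, P = P / s, meta = meta), class = "DistanceDistribution")
}

#' @export
print.DistanceDistribution <- function(x, ...) {
  m <- sum(x$r * x$P) * (x$r[2] - x$r[1])
  cat(sprintf("<DistanceDistribution: %d bins on [%.1f, %.1f] A, mean %.1f A>\n",
              length(x$r), min(x$r), max(x$r), m))
  invisible(x)
}

#' Inter-label distance distribution
#'
#' For every unordered pair of labels, every rotamer pair contributes mass
#' w_Ai * w_Bj at the spin-center distance; contributions are summed over
#' all pairs (the cumulative multi-pair distribution), smoothed with a
#' Gaussian kernel of width `smooth_sigma` (0 = raw histogram), then
#' normalized once to unit integral. Distances outside the grid are clipped
#' to the nearest edge bin with a warning.
#'
#' @param labels list of two or more `SpinLabel` objects.
#' @param r_grid uniform distance grid (Angstrom); default 0-100 A, 0.5 A.
#' @param smooth_sigma Gaussian kernel width (Angstrom).
#' @return a `DistanceDistribution`.
#' @export
distance_distribution <- function(labels, r_grid = seq(0, 100, by = 0.5),
                                  smooth_sigma = 0.5) {
  if (length(labels) < 2) stop("need at least 2 labels", call. = FALSE)
  dr <- r_grid[2] - r_grid[1]
  stopifnot(all(abs(diff(r_grid) - dr) < 1e-9))
  dvals <- numeric(); wvals <- numeric()
  for (i in seq_len(length(labels) - 1)) for (j in (i + 1):length(labels)) {
    ca <- spin_centers(labels[[i]]); cb <- spin_centers(labels[[j]])
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * ca %*% t(cb)
    d <- sqrt(pmax(d2, 0))
    w <- outer(labels[[i]]$weights, labels[[j]]$weights)
    dvals <- c(dvals, as.numeric(d)); wvals <- c(wvals, as.numeric(w))
  }
  out_of_grid <- dvals < min(r_grid) | dvals > max(r_grid)
  if (any(out_of_grid))
    warning(sprintf("%d rotamer-pair distance(s) outside the grid clipped to edge bins",
                    sum(out_of_grid)))
  dvals <- pmin(pmax(dvals, min(r_grid)), max(r_grid))
  if (smooth_sigma > 0) {
    P <- vapply(r_grid, function(r)
      sum(wvals * stats::dnorm(r, dvals, smooth_sigma)), 0)
  } else {
    bins <- round((dvals - r_grid[1]) / dr) + 1
    P <- numeric(length(r_grid))
    for (k in seq_along(bins)) P[bins[k]] <- P[bins[k]] + wvals[k]
    P <- P / dr
  }
  new_distance_distribution(r_grid, P,
    meta = list(n_labels = length(labels), smooth_sigma = smooth_sigma))
}

#' 1-D Wasserstein (earth-mover's) distance on a shared grid
#'
#' W1 = sum |CDF_P - CDF_Q| * dr. Symmetric, zero iff P = Q, and equal to
#' the translation distance for shifted deltas.
#'
#' @param P,Q `DistanceDistribution` objects on the same grid, or plain
#'   density vectors together with `r`.
#' @param r optional shared grid when P and Q are plain vectors.
#' @return distance in Angstrom.
#' @export
wasserstein_1d <- function(P, Q, r = NULL) {
  if (inherits(P, "DistanceDistribution")) { r <- P$r; P <- P$P }
  if (inherits(Q, "DistanceDistribution")) {
    if (length(Q$r) != length(r) || any(abs(Q$r - r) > 1e-9))
      stop("grid mismatch between distributions", call. = FALSE)
    Q <- Q$P
  }
  if (is.null(r) || length(P) != length(Q) || length(P) != length(r))
    stop("grid mismatch between distributions", call. = FALSE)
  dr <- r[2] - r[1]
  sum(abs(cumsum(P) - cumsum(Q))) * dr^2
}

#' Export a distance distribution as two-column text
#' @param dist a `DistanceDistribution`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_distribution <- function(dist, path) {
  utils::write.table(data.frame(r = dist$r, P = dist$P), path,
                     row.names = FALSE, col.names = c("r", "P"), quote = FALSE)
  invisible(path)
}

#' Solvent-exposed candidate labeling sites
#'
#' Residues whose summed side-chain SASA (computed in the context of the
#' full structure) strictly exceeds the threshold. Glycines are excluded
#' (no side chain); waters are ignored entirely.
#'
#' @param structure a `StructureModel`.
#' @param subset optional `AtomSubset` restricting the candidate residues.
#' @param threshold SASA threshold in square Angstrom (default 50).
#' @param params an `lj_params` (radii table, probe, n_points).
#' @return data frame with chain, resnum, resname, sasa; only passing sites.
#' @export
solvent_exposed_sites <- function(structure, subset = NULL, threshold = 50,
                                  params = lj_params()) {
  a <- structure$atoms
  keep <- which(!(a$resname %in% c("HOH", "WAT")))
  co <- structure$coords[[1]][keep, , drop = FALSE]
  rad <- sasa_radii(a$element[keep], params$table)
  sasa <- shrake_rupley_sasa(co, rad, params$sasa_probe, params$sasa_n_points)
  cand <- if (is.null(subset)) keep else intersect(keep, subset$idx)
  resid <- unique(a[cand, c("chain", "resnum", "resname")])
  rows <- lapply(seq_len(nrow(resid)), function(k) {
    ch <- resid$chain[k]; rn <- resid$resnum[k]
    if (resid$resname[k] == "GLY") return(NULL)
    i <- which(a$chain[keep] == ch & a$resnum[keep] == rn &
                 !(a$name[keep] %in% c("N", "CA", "C", "O")))
    if (!length(i)) return(NULL)
    data.frame(chain = ch, resnum = rn, resname = resid$resname[k],
               sasa = sum(sasa[i]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[tab$sasa > threshold, , drop = FALSE]
}

#' Screen site pairs for distance-distribution contrast between two states
#'
#' Models a label at every solvent-exposed site (in both states), predicts
#' the intra-state distance distribution for every site pair, and ranks the
#' pairs by the earth-mover's distance between the two states' distributions.
#'
#' @param structure_a,structure_b two conformations sharing residue numbering.
#' @param library a `RotamerLibrary`.
#' @param sasa_threshold site screen threshold (square Angstrom).
#' @param params an `lj_params`.
#' @param r_grid,smooth_sigma distance-distribution settings.
#' @param ... further arguments passed to [attach_label()].
#' @return list of class `PairScreenResult`: `pairs` (data frame sorted by
#'   descending emd), `sasa` (per-site table), `labels_a`, `labels_b`.
#' @export
pair_screen <- function(structure_a, structure_b, library,
                        sasa_threshold = 50, params = lj_params(),
                        r_grid = seq(0, 100, by = 0.5), smooth_sigma = 0.5,
                        ...) {
  sa <- solvent_exposed_sites(structure_a, threshold = sasa_threshold,
                              params = params)
  sb <- solvent_exposed_sites(structure_b, threshold = sasa_threshold,
                              params = params)
  key <- function(t) paste(t$chain, t$resnum)
  common <- intersect(key(sa), key(sb))
  sites <- sa[key(sa) %in% common, c("chain", "resnum")]
  la <- list(); lb <- list(); ok <- logical(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    ch <- sites$chain[k]; rn <- sites$resnum[k]
    ra <- try(attach_label(library, structure_a, ch, rn, params = params, ...),
              silent = TRUE)
    rb <- try(attach_label(library, structure_b, ch, rn, params = params, ...),
              silent = TRUE)
    if (inherits(ra, "try-error") || inherits(rb, "try-error")) {
      warning(sprintf("site %s%d skipped: attachment failed in one state", ch, rn))
      next
    }
    la[[k]] <- ra; lb[[k]] <- rb; ok[k] <- TRUE
  }
  idx <- which(ok)
  pairs <- list()
  for (u in seq_along(idx)) for (v in seq_along(idx)) {
    if (v <= u) next
    i <- idx[u]; j <- idx[v]
    da <- distance_distribution(list(la[[i]], la[[j]]), r_grid, smooth_sigma)
    db <- distance_distribution(list(lb[[i]], lb[[j]]), r_grid, smooth_sigma)
    pairs[[length(pairs) + 1]] <- data.frame(
      chain_i = sites$chain[i], resnum_i = sites$resnum[i],
      chain_j = sites$chain[j], resnum_j = sites$resnum[j],
      emd = wasserstein_1d(da, db), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, pairs)
  tab <- tab[order(-tab$emd), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(pairs = tab, sasa = sa[key(sa) %in% common, , drop = FALSE],
                 labels_a = la[idx], labels_b = lb[idx],
                 sites = sites[idx, , drop = FALSE]),
            class = "PairScreenResult")
}
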