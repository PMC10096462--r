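# Shared fixtures and independent oracle implementations. The oracles
# deliberately take different routes than the package code they check.

toy_lib <- make_toy_label_library()
helix10 <- make_helix(10)

cross_o <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# Independent torsion formula: project the outer bonds onto the plane
# normal to the central bond, then take the signed angle between them.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  u <- p1 - p2; w <- p4 - p3
  b2h <- b2 / sqrt(sum(b2^2))
  up <- u - sum(u * b2h) * b2h
  wp <- w - sum(w * b2h) * b2h
  atan2(sum(cross_o(up, wp) * b2h), sum(up * wp)) * 180 / pi
}

# Independent rotation about an arbitrary axis via quaternions.
oracle_rotate <- function(points, axis, theta_deg, origin) {
  th <- theta_deg * pi / 180
  ax <- axis / sqrt(sum(axis^2))
  q <- c(cos(th / 2), sin(th / 2) * ax)
  qmul <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + cross_o(a[2:4], b[2:4]))
  t(apply(points, 1, function(p) {
    v <- c(0, p - origin)
    r <- qmul(qmul(q, v), c(q[1], -q[2:4]))
    r[2:4] + origin
  }))
}

# Exact 1-D optimal transport through the quantile coupling: merge the two
# CDFs' breakpoints and integrate |quantile difference| in u.
oracle_w1 <- function(P, Q, r) {
  dr <- r[2] - r[1]
  mp <- P * dr; mq <- Q * dr
  cp <- cumsum(mp) / sum(mp); cq <- cumsum(mq) / sum(mq)
  u <- sort(unique(round(c(0, cp, cq), 15)))
  qf <- function(cdf, uu) r[findInterval(uu, cdf, left.open = TRUE) + 1]
  tot <- 0
  for (s in seq_len(length(u) - 1)) {
    mid <- (u[s] + u[s + 1]) / 2
    tot <- tot + (u[s + 1] - u[s]) * abs(qf(cp, mid) - qf(cq, mid))
  }
  tot
}

# Naive pair-enumeration clash score, plain loops, no vectorization.
oracle_lj <- function(coords, elements, env_co, env_el, params) {
  tab <- params$table
  total <- 0
  for (i in seq_len(nrow(coords))) for (j in seq_len(nrow(env_co))) {
    r <- sqrt(sum((coords[i, ] - env_co[j, ])^2))
    if (r > params$cutoff) next
    ti <- tab[tab$element == elements[i], ]
    tj <- tab[tab$element == env_el[j], ]
    rmin <- ti$rmin2 + tj$rmin2
    eps <- sqrt(ti$eps * tj$eps)
    total <- total + min(params$cap, eps * (params$forgive * rmin / r)^12)
  }
  total
}

# Minimal hand-rolled PDB text for parser edge cases.
pdb_line <- function(serial, name, resname, chain, resnum, x, y, z,
                     occ = 1, b = 0, elem = substr(name, 1, 1),
                     record = "ATOM", altloc = " ") {
  sprintf("%-6s%5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resnum, x, y, z,
          occ, b, elem)
}

# Tiny 3-residue scaffold plus controllable foreign probe atoms, for
# single-pair energy oracles.
probe_structure <- function(probes = NULL) {
  h <- make_helix(3)
  if (is.null(probes)) return(h)
  a <- h$atoms
  n0 <- nrow(a)
  pa <- data.frame(serial = n0 + seq_len(nrow(probes)), name = "PRB",
                   element = probes$element, resname = "PRB",
                   resnum = 900L + seq_len(nrow(probes)), chain = "Z",
                   occ = 1, b = 0, stringsAsFactors = FALSE)
  spinlabelr:::new_structure_model(
    rbind(a, pa), list(rbind(h$coords[[1]], as.matrix(probes[, c("x", "y", "z")]))),
    "probe")
}
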