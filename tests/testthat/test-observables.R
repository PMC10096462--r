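# Hand-built label objects with fully controlled geometry.
fake_label <- function(centers, weights, spin_xyz = NULL) {
  # one spin atom per rotamer placed at the requested center
  nr <- nrow(centers)
  co <- array(0, c(nr, 2, 3))
  for (r in seq_len(nr)) {
    co[r, 1, ] <- centers[r, ] + c(5, 5, 5)  # a heavy non-spin atom
    co[r, 2, ] <- centers[r, ]
  }
  list(atom_names = c("CB", "NO"), elements = c("C", "N"), coords = co,
       weights = weights / sum(weights), spin_atoms = "NO", spin_weights = 1,
       spin_idx = 2L, site = list(chain = "A", resnum = 1))
}

test_that("spin centers and centroids are the stated weighted means", {
  lab <- attach_label(toy_lib, helix10, "A", 5, eval_clash = FALSE)
  sc <- spin_centers(lab)
  iN1 <- match("N1", lab$atom_names); iO1 <- match("O1", lab$atom_names)
  # equal spin weights: midpoint of N1/O1 per rotamer
  for (r in 1:3)
    expect_equal(sc[r, ], (lab$coords[r, iN1, ] + lab$coords[r, iO1, ]) / 2)
  expect_equal(spin_centroid(lab), as.numeric(crossprod(sc, lab$weights)))

  # unequal random spin weights against a plain arithmetic oracle
  set.seed(9)
  lab2 <- lab
  lab2$spin_weights <- c(0.8, 0.2)
  sc2 <- spin_centers(lab2)
  for (r in 1:3)
    expect_equal(sc2[r, ], 0.8 * lab2$coords[r, iN1, ] + 0.2 * lab2$coords[r, iO1, ])

  # two synthetic rotamers, weights (0.75, 0.25), centers on the x-axis
  fl <- fake_label(rbind(c(0, 0, 0), c(4, 0, 0)), c(0.75, 0.25))
  expect_equal(spin_centroid(fl), c(1, 0, 0))
  # single rotamer: centroid = its center
  f1 <- fake_label(rbind(c(2, -1, 3)), 1)
  expect_equal(spin_centroid(f1), c(2, -1, 3))
})

test_that("ensemble_centroid averages heavy atoms only", {
  lab <- attach_label(toy_lib, helix10, "A", 5, eval_clash = FALSE)
  withH <- lab
  withH$elements <- c(lab$elements[1:8], "H")  # pretend O1 is a hydrogen
  heavy_mean <- t(vapply(1:3, function(r) colMeans(lab$coords[r, 1:8, ]),
                         numeric(3)))
  expect_equal(ensemble_centroid(withH),
               as.numeric(crossprod(heavy_mean, lab$weights)))
})

test_that("distance_distribution: delta, enumeration oracle, invariances", {
  a <- fake_label(rbind(c(0, 0, 0)), 1)
  b <- fake_label(rbind(c(20, 0, 0)), 1)
  dd <- distance_distribution(list(a, b), smooth_sigma = 0)
  expect_equal(dd$r[which.max(dd$P)], 20)
  expect_equal(sum(dd$P) * 0.5, 1, tolerance = 1e-6)

  # 2x2 rotamers: four-term weighted histogram
  A <- fake_label(rbind(c(0, 0, 0), c(1, 0, 0)), c(0.6, 0.4))
  B <- fake_label(rbind(c(30, 0, 0), c(35, 0, 0)), c(0.7, 0.3))
  r_grid <- seq(0, 100, 0.5)
  dd2 <- distance_distribution(list(A, B), r_grid, smooth_sigma = 0)
  dists <- c(30, 35, 29, 34)
  w <- c(0.6 * 0.7, 0.6 * 0.3, 0.4 * 0.7, 0.4 * 0.3)
  expected <- numeric(length(r_grid))
  for (k in 1:4) {
    bin <- round(dists[k] / 0.5) + 1
    expected[bin] <- expected[bin] + w[k]
  }
  expected <- expected / 0.5
  expect_equal(dd2$P, expected / (sum(expected) * 0.5), tolerance = 1e-12)

  # label order permutation invariance
  dd3 <- distance_distribution(list(B, A), r_grid, smooth_sigma = 0)
  expect_equal(dd2$P, dd3$P)

  # smoothing preserves normalization and the mean within one bin
  dds <- distance_distribution(list(A, B), r_grid, smooth_sigma = 1.2)
  expect_equal(sum(dds$P) * 0.5, 1, tolerance = 1e-6)
  m_raw <- sum(dd2$r * dd2$P) * 0.5
  m_sm <- sum(dds$r * dds$P) * 0.5
  expect_lt(abs(m_raw - m_sm), 0.5)

  # out-of-grid mass is clipped to the edge with a warning
  far <- fake_label(rbind(c(500, 0, 0)), 1)
  expect_warning(ddc <- distance_distribution(list(a, far), smooth_sigma = 0),
                 "clipped")
  expect_equal(ddc$r[which.max(ddc$P)], 100)
  expect_error(distance_distribution(list(a)), "at least 2")
})

test_that("wasserstein_1d agrees with the quantile-coupling oracle", {
  r <- seq(0, 100, 0.5)
  delta_at <- function(x) {
    P <- numeric(length(r)); P[round(x / 0.5) + 1] <- 2; P
  }
  expect_equal(wasserstein_1d(delta_at(30), delta_at(30), r), 0)
  expect_equal(wasserstein_1d(delta_at(30), delta_at(40), r), 10)

  set.seed(14)
  rs <- seq(0, 10, length.out = 20)  # <= 20 bins for the oracle
  for (k in 1:8) {
    P <- runif(20); P <- P / (sum(P) * diff(rs)[1])
    Q <- runif(20); Q <- Q / (sum(Q) * diff(rs)[1])
    expect_equal(wasserstein_1d(P, Q, rs), oracle_w1(P, Q, rs),
                 tolerance = 1e-9)
    expect_equal(wasserstein_1d(P, Q, rs), wasserstein_1d(Q, P, rs))
  }
  # triangle inequality on random triples
  for (k in 1:10) {
    P <- runif(20); Q <- runif(20); S <- runif(20)
    P <- P / sum(P); Q <- Q / sum(Q); S <- S / sum(S)
    expect_lte(wasserstein_1d(P, Q, rs),
               wasserstein_1d(P, S, rs) + wasserstein_1d(S, Q, rs) + 1e-12)
  }
  expect_error(wasserstein_1d(runif(10), runif(20), rs), "grid mismatch")
})

test_that("solvent_exposed_sites equals a brute-force per-residue filter", {
  tab <- solvent_exposed_sites(helix10, threshold = 20)
  p <- lj_params()
  a <- helix10$atoms
  sasa <- shrake_rupley_sasa(helix10$coords[[1]],
                             spinlabelr:::sasa_radii(a$element, p$table),
                             p$sasa_probe, p$sasa_n_points)
  expected <- vapply(1:10, function(rn)
    sum(sasa[a$resnum == rn & !(a$name %in% c("N", "CA", "C", "O"))]), 0)
  want <- which(expected > 20)
  expect_setequal(tab$resnum, want)
  expect_equal(tab$sasa[order(tab$resnum)], expected[want], tolerance = 1e-9)

  # glycine (no side chain) is never reported
  g <- helix10
  g$atoms$resname[g$atoms$resnum == 5] <- "GLY"
  tg <- solvent_exposed_sites(g, threshold = 0)
  expect_false(5 %in% tg$resnum)
})

test_that("pair_screen ranks site pairs by distance-distribution contrast", {
  hg <- make_hinge(16, 70)
  # identical states: every EMD is zero
  ps0 <- pair_screen(hg$a, hg$a, toy_lib)
  expect_true(all(abs(ps0$pairs$emd) < 1e-12))

  ps <- pair_screen(hg$a, hg$b, toy_lib)
  expect_true(all(diff(ps$pairs$emd) <= 1e-12))  # sorted descending
  top <- ps$pairs[1, ]
  expect_true((top$resnum_i <= hg$hinge_res - 1) !=
                (top$resnum_j <= hg$hinge_res - 1))

  # brute-force recomputation of the top pair's EMD
  la_i <- attach_label(toy_lib, hg$a, top$chain_i, top$resnum_i)
  la_j <- attach_label(toy_lib, hg$a, top$chain_j, top$resnum_j)
  lb_i <- attach_label(toy_lib, hg$b, top$chain_i, top$resnum_i)
  lb_j <- attach_label(toy_lib, hg$b, top$chain_j, top$resnum_j)
  da <- distance_distribution(list(la_i, la_j))
  db <- distance_distribution(list(lb_i, lb_j))
  expect_equal(top$emd, wasserstein_1d(da, db), tolerance = 1e-9)
  expect_equal(top$emd, oracle_w1(da$P, db$P, da$r), tolerance = 1e-6)
})
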