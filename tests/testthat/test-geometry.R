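test_that("measure_dihedral: planar cases, oracle agreement, degeneracy", {
  expect_equal(measure_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(measure_dihedral(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 180)
  set.seed(42)
  for (k in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(measure_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(
    measure_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear")
})

test_that("set_dihedral rotates downstream atoms only, preserving geometry", {
  lib <- toy_lib
  co <- lib$coords[1, , ]
  q1 <- lib$dihedral_quads[[1]]; d1 <- lib$downstream[[1]]
  q2 <- lib$dihedral_quads[[2]]; d2 <- lib$downstream[[2]]

  # identity: setting to the current value changes nothing
  cur <- measure_dihedral(co[q1[1], ], co[q1[2], ], co[q1[3], ], co[q1[4], ])
  expect_lt(max(abs(set_dihedral(co, q1, d1, cur) - co)), 1e-9)

  co73 <- set_dihedral(co, q1, d1, 73)
  expect_equal(measure_dihedral(co73[q1[1], ], co73[q1[2], ], co73[q1[3], ],
                                co73[q1[4], ]), 73, tolerance = 1e-6)
  # atoms not downstream unchanged exactly
  fixed <- setdiff(seq_len(nrow(co)), d1)
  expect_identical(co73[fixed, ], co[fixed, ])
  # chained dihedral rides rigidly: its value is unchanged
  chi2_before <- measure_dihedral(co[q2[1], ], co[q2[2], ], co[q2[3], ], co[q2[4], ])
  chi2_after <- measure_dihedral(co73[q2[1], ], co73[q2[2], ], co73[q2[3], ],
                                 co73[q2[4], ])
  expect_equal(chi2_after, chi2_before, tolerance = 1e-9)
  # bond lengths and angles untouched
  d0 <- as.matrix(dist(co)); d73 <- as.matrix(dist(co73))
  bonds <- which(d0 < 2 & d0 > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(bonds)))
    expect_equal(d73[bonds[k, 1], bonds[k, 2]], d0[bonds[k, 1], bonds[k, 2]],
                 tolerance = 1e-6)
  expect_error(set_dihedral(co, c(1, 1, 2, 3), d1, 10), "degenerate|coincident")
})

make_triad <- function(angle_deg, bN = 1.458, bC = 1.525) {
  a <- angle_deg * pi / 180
  list(N = c(bN * cos(a / 2), bN * sin(a / 2), 0),
       CA = c(0, 0, 0),
       C = c(bC * cos(a / 2), -bC * sin(a / 2), 0))
}

test_that("bisect superposition aligns CA, bisector and plane normal", {
  t1 <- make_triad(110)
  id <- bisect_superposition(t1$N, t1$CA, t1$C, t1$N, t1$CA, t1$C)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-9)

  # recover an arbitrary rigid motion when triad geometries are equal
  set.seed(7)
  axis <- rnorm(3); theta <- 67
  shift <- c(3, -2, 5)
  dst <- lapply(t1, function(p)
    as.numeric(oracle_rotate(rbind(p), axis, theta, c(0, 0, 0))) + shift)
  tf <- bisect_superposition(t1$N, t1$CA, t1$C, dst$N, dst$CA, dst$C)
  for (nm in names(t1))
    expect_equal(apply_transform(tf, t1[[nm]]), dst[[nm]], tolerance = 1e-9)

  # different N-CA-C angles: CA exact, N and C split symmetrically
  t2 <- make_triad(114)
  tf2 <- bisect_superposition(t1$N, t1$CA, t1$C, t2$N, t2$CA, t2$C)
  expect_equal(apply_transform(tf2, t1$CA), t2$CA, tolerance = 1e-12)
  dN <- sqrt(sum((apply_transform(tf2, t1$N) - t2$N)^2))
  dC <- sqrt(sum((apply_transform(tf2, t1$C) - t2$C)^2))
  expect_gt(dN, 1e-4)
  expect_equal(dN / 1.458, dC / 1.525, tolerance = 1e-6)  # symmetric angular split
  expect_error(bisect_superposition(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0),
                                    t1$N, t1$CA, t1$C), "degenerate")
})

test_that("triad (Kabsch) superposition recovers rigid motions, det +1 always", {
  t1 <- make_triad(110)
  id <- triad_superposition(t1$N, t1$CA, t1$C, t1$N, t1$CA, t1$C)
  expect_equal(id$R, diag(3), tolerance = 1e-9)

  set.seed(8)
  ax <- rnorm(3)
  dst <- lapply(t1, function(p)
    as.numeric(oracle_rotate(rbind(p), ax, -39, c(1, 1, 1))) + c(0, 4, -1))
  tf <- triad_superposition(t1$N, t1$CA, t1$C, dst$N, dst$CA, dst$C)
  rmsd <- sqrt(mean(vapply(names(t1), function(nm)
    sum((apply_transform(tf, t1[[nm]]) - dst[[nm]])^2), 0)))
  expect_lt(rmsd, 1e-9)
  expect_equal(det(tf$R), 1, tolerance = 1e-9)

  # mirrored target: still a proper rotation, nonzero residual
  mir <- lapply(t1, function(p) p * c(1, 1, -1))
  mir$N <- mir$N + c(0, 0, 0.3)  # break exact planarity so reflection is needed
  tfm <- triad_superposition(t1$N, t1$CA, t1$C, mir$N, mir$CA, mir$C)
  expect_equal(det(tfm$R), 1, tolerance = 1e-9)

  # bisect and triad agree exactly when internal geometries are identical
  tfb <- bisect_superposition(t1$N, t1$CA, t1$C, dst$N, dst$CA, dst$C)
  expect_equal(tf$R, tfb$R, tolerance = 1e-6)
  expect_equal(tf$t, tfb$t, tolerance = 1e-6)
})

test_that("build_coords_from_internal reproduces stored rotamers deterministically", {
  for (r in 1:3) {
    co <- build_coords_from_internal(toy_lib, toy_lib$dihedrals[r, ])
    expect_lt(max(abs(co - toy_lib$coords[r, , ])), 1e-3)
  }
  a <- build_coords_from_internal(toy_lib, c(10, -120))
  b <- build_coords_from_internal(toy_lib, c(10, -120))
  expect_identical(a, b)
  # requested dihedrals are realized exactly
  for (k in 1:2) {
    q <- toy_lib$dihedral_quads[[k]]
    expect_equal(measure_dihedral(a[q[1], ], a[q[2], ], a[q[3], ], a[q[4], ]),
                 c(10, -120)[k], tolerance = 1e-6)
  }
  expect_error(build_coords_from_internal(toy_lib, 5), "one dihedral value")
})
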