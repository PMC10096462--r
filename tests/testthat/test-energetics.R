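# A one-rotamer, one-atom "ensemble" for direct pair-energy checks.
single_atom_ensemble <- function(element = "C", at = c(0, 0, 0)) {
  co <- array(0, c(1, 4, 3))
  co[1, 1, ] <- c(-1.2, 1, 0); co[1, 2, ] <- c(0, 0, 0)
  co[1, 3, ] <- c(1.2, 1, 0); co[1, 4, ] <- at
  list(atom_names = c("N", "CA", "C", "X1"), elements = c("N", "C", "C", element),
       coords = co, weights = 1)
}

probe_env <- function(element, at) {
  s <- probe_structure(data.frame(element = element,
                                  x = at[1], y = at[2], z = at[3]))
  select_atoms(s, "chain Z")
}

test_that("flat-top repulsive LJ matches its closed form pair by pair", {
  p <- lj_params()
  tab <- p$table
  eps_cc <- tab$eps[tab$element == "C"]
  rmin_cc <- 2 * tab$rmin2[tab$element == "C"]
  # pair at r = f * rmin: ratio term is exactly 1 -> energy = eps
  r0 <- p$forgive * rmin_cc
  e <- flat_top_repulsive_lj(single_atom_ensemble("C", c(r0, 30, 0)),
                             probe_env("C", c(0, 30, 0)), p)
  expect_equal(e, eps_cc, tolerance = 1e-12)
  # beyond cutoff: zero
  e0 <- flat_top_repulsive_lj(single_atom_ensemble("C", c(p$cutoff + 0.1, 30, 0)),
                              probe_env("C", c(0, 30, 0)), p)
  expect_equal(e0, 0)
  # near-contact: capped
  ec <- flat_top_repulsive_lj(single_atom_ensemble("C", c(0.1, 30, 0)),
                              probe_env("C", c(0, 30, 0)), p)
  expect_equal(ec, p$cap)
  expect_error(
    flat_top_repulsive_lj(single_atom_ensemble("Xx", c(3, 30, 0)),
                          probe_env("C", c(0, 30, 0)), p),
    "unknown element.*Xx")
})

test_that("energies are monotone in the forgive factor", {
  set.seed(11)
  lab <- attach_label(toy_lib, helix10, "A", 5, eval_clash = FALSE)
  env <- spinlabelr:::clash_environment(helix10, "A", 5)
  fs <- c(0.6, 0.75, 0.9, 1.0, 1.1)
  es <- sapply(fs, function(f)
    flat_top_repulsive_lj(lab, env, lj_params(forgive = f)))
  for (k in seq_len(length(fs) - 1))
    expect_true(all(es[, k] <= es[, k + 1] + 1e-12))
})

test_that("reweight: closed forms, shift invariance, composition", {
  expect_equal(reweight(c(0.3, 0.7), c(5, 5), 0.593), c(0.3, 0.7))
  kT <- 0.593
  expect_equal(reweight(c(0.5, 0.5), c(0, kT * log(2)), kT), c(2 / 3, 1 / 3))
  expect_equal(reweight(1, 42, kT), 1)
  set.seed(3)
  w <- runif(5); w <- w / sum(w)
  e1 <- rnorm(5); e2 <- rnorm(5)
  expect_equal(reweight(w, e1 + 7.7, kT), reweight(w, e1, kT))
  expect_equal(reweight(reweight(w, e1, kT), e2, kT),
               reweight(w, e1 + e2, kT))
  # degenerate: all mass sits on rotamers with zero prior
  expect_error(reweight(c(0, 1), c(0, 1e6), 1e-9), "underflow|degenerate")
})

test_that("trim keeps the minimal high-weight prefix and renormalizes", {
  t0 <- trim_weights(c(0.5, 0.5, 0), 0)
  expect_equal(t0$keep, c(1, 2))
  t1 <- trim_weights(c(0.9, 0.06, 0.04), 0.005)
  expect_equal(t1$keep, 1:3)
  t2 <- trim_weights(c(0.998, 0.001, 0.001), 0.005)
  expect_equal(t2$keep, 1)
  expect_equal(t2$weights, 1)
  # relative weights among survivors preserved
  t3 <- trim_weights(c(0.6, 0.3, 0.06, 0.04), 0.1)
  expect_equal(t3$weights, c(0.6, 0.3) / 0.9)
})

test_that("Shrake-Rupley SASA matches analytic sphere results", {
  # isolated atom: full expanded sphere
  a <- shrake_rupley_sasa(matrix(0, 1, 3), 1.6, probe = 1.4, n_points = 960)
  expect_equal(a, 4 * pi * 3^2, tolerance = 0.02 * 4 * pi * 9)
  # atom caged inside a tight shell of neighbors: zero
  dirs <- spinlabelr:::sphere_points(30) * 2
  caged <- shrake_rupley_sasa(rbind(c(0, 0, 0), dirs),
                              c(1.6, rep(1.6, 30)), 1.4, 256)
  expect_equal(caged[1], 0)
  # two equal spheres: analytic spherical-cap formula
  r <- 1.6; probe <- 1.4; R <- r + probe; d <- 2.5
  a2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(r, r), probe, 4096)
  h <- R - d / 2
  analytic <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(a2[1], analytic, tolerance = 0.02 * analytic)
  expect_equal(a2[2], analytic, tolerance = 0.02 * analytic)
  # adding a neighbor never increases any atom's area
  set.seed(21)
  pts <- matrix(rnorm(30, sd = 2.5), 10, 3)
  base <- shrake_rupley_sasa(pts, rep(1.7, 10), 1.4, 256)
  more <- shrake_rupley_sasa(rbind(pts, c(0.5, 0.5, 0.5)), rep(1.7, 11), 1.4, 256)
  expect_true(all(more[1:10] <= base + 1e-9))
})

test_that("SASA-augmented energy reduces to LJ and penalizes burial", {
  lab <- attach_label(toy_lib, helix10, "A", 5, eval_clash = FALSE)
  env <- spinlabelr:::clash_environment(helix10, "A", 5)
  p <- lj_params()
  expect_equal(sasa_augmented_energy(lab, env, p, w_sasa = 0),
               flat_top_repulsive_lj(lab, env, p))
  # compare the same rotamer with and without a loose probe cage around its
  # terminal atom: burial forfeits the SASA reward, raising the energy
  term <- lab$coords[1, 9, ]
  cage <- sweep(spinlabelr:::sphere_points(40) * 4.4, 2, term, `+`)
  s <- probe_structure(data.frame(element = "C", x = cage[, 1], y = cage[, 2],
                                  z = cage[, 3]))
  env_cage <- select_atoms(s, "chain Z")
  e_cage <- sasa_augmented_energy(lab, env_cage, p, w_sasa = 0.05)
  e_free <- sasa_augmented_energy(lab, spinlabelr:::new_atom_subset(s, 1),
                                  p, w_sasa = 0.05)
  expect_gt(e_cage[1], e_free[1])  # burial costs SASA reward
})
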