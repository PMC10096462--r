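# RotamerLibrary: a template side-chain ensemble. Rotamers share one topology
# (atom names/elements, bond graph) and differ in their mobile dihedrals --
# plus any stereoisomeric heterogeneity retained verbatim from the source
# conformers. Coordinates live in a canonical local frame: CA at the origin,
# the N-CA-C bisector along +x, the N-CA-C plane normal along +z.

BACKBONE_NAMES <- c("N", "CA", "C", "O")

# Geometric bond inference; input PDBs may lack CONECT records.
# Heavy-atom pairs within 1.9 A are bonded, hydrogens within 1.2 A.
infer_bonds <- function(coords, elements) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  cut <- matrix(1.9, n, n)
  ish <- elements == "H"
  cut[ish, ] <- 1.2
  cut[, ish] <- 1.2
  cut[ish, ish] <- 0  # no H-H bonds
  adj <- d > 1e-6 & d <= cut
  which(adj & upper.tri(adj), arr.ind = TRUE)
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

# Atoms on the far side of the q2-q3 bond (component containing q3 after
# cutting the edge), excluding q3 itself: these ride rigidly with a dihedral.
downstream_atoms <- function(adj, q2, q3) {
  seen <- rep(FALSE, length(adj))
  seen[q2] <- TRUE
  stack <- q3
  seen[q3] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  setdiff(which(seen), c(q2, q3))
}

# Build-order and reference triples for internal coordinates. Roots are
# N, CA, C; every later atom is defined against three already-placed atoms,
# walking the bond graph. Fourth atoms of mobile dihedrals use exactly the
# quadruplet's first three atoms as references so that overriding those
# entries reproduces the mobile-dihedral parameterization.
ic_table <- function(atom_names, adj, dihedral_quads) {
  n <- length(atom_names)
  iN <- match("N", atom_names); iCA <- match("CA", atom_names)
  iC <- match("C", atom_names)
  if (anyNA(c(iN, iCA, iC)))
    stop("library invalid: backbone N/CA/C required", call. = FALSE)
  order <- c(iN, iCA, iC)
  refs <- matrix(NA_integer_, n, 3)
  placed <- rep(FALSE, n); placed[order] <- TRUE
  pred <- rep(NA_integer_, n)
  pred[iCA] <- iN; pred[iC] <- iCA
  forced <- list()
  if (length(dihedral_quads))
    for (q in dihedral_quads) forced[[as.character(q[4])]] <- q[1:3]
  forced_idx <- as.integer(names(forced))
  repeat {
    progress <- FALSE
    # forced (mobile-dihedral fourth) atoms first: siblings sharing their
    # pivot are then defined relative to them and ride when the dihedral turns
    for (i in c(forced_idx, setdiff(seq_len(n), forced_idx))) {
      if (placed[i]) next
      nb <- adj[[i]][placed[adj[[i]]]]
      if (!length(nb)) next
      f <- forced[[as.character(i)]]
      if (!is.null(f)) {
        if (!all(placed[f])) next
        refs[i, ] <- c(f[3], f[2], f[1])
      } else {
        p <- nb[1]
        g <- pred[p]
        if (is.na(g) || !placed[g]) g <- setdiff(adj[[p]][placed[adj[[p]]]], i)[1]
        if (is.na(g)) next
        sib <- which(placed & !is.na(pred) & pred == p)
        sib <- setdiff(sib, c(i, g))
        gg <- if (length(sib)) sib[length(sib)] else pred[g]
        if (is.na(gg) || gg == p || !placed[gg])
          gg <- setdiff(adj[[g]][placed[adj[[g]]]], c(i, p))[1]
        if (is.na(gg)) gg <- setdiff(which(placed), c(i, p, g))[1]
        if (is.na(gg)) next
        refs[i, ] <- c(p, g, gg)
      }
      pred[i] <- refs[i, 1]
      placed[i] <- TRUE
      order <- c(order, i)
      progress <- TRUE
    }
    if (all(placed)) break
    if (!progress)
      stop("library invalid: internal-coordinate table incomplete (disconnected atoms)",
           call. = FALSE)
  }
  list(order = order, refs = refs, roots = c(iN, iCA, iC))
}

measure_ic <- function(coords, ic) {
  n <- nrow(coords)
  bond <- angle <- dihedral <- rep(NA_real_, n)
  for (i in ic$order[-(1:3)]) {
    r <- ic$refs[i, ]
    bond[i] <- vnorm(coords[i, ] - coords[r[1], ])
    v1 <- coords[i, ] - coords[r[1], ]
    v2 <- coords[r[2], ] - coords[r[1], ]
    angle[i] <- acos(max(-1, min(1, sum(unit(v1) * unit(v2))))) * 180 / pi
    dihedral[i] <- measure_dihedral(coords[r[3], ], coords[r[2], ],
                                    coords[r[1], ], coords[i, ])
  }
  # root internal geometry: N-CA bond, CA-C bond, N-CA-C angle
  iN <- ic$roots[1]; iCA <- ic$roots[2]; iC <- ic$roots[3]
  list(bond = bond, angle = angle, dihedral = dihedral,
       root = list(b_NCA = vnorm(coords[iN, ] - coords[iCA, ]),
                   b_CAC = vnorm(coords[iC, ] - coords[iCA, ]),
                   a_NCAC = acos(max(-1, min(1,
                     sum(unit(coords[iN, ] - coords[iCA, ]) *
                         unit(coords[iC, ] - coords[iCA, ]))))) * 180 / pi))
}

# Express coordinates in the canonical local frame of their own N/CA/C triad.
to_local_frame <- function(coords, iN, iCA, iC) {
  F <- triad_frame(coords[iN, ], coords[iCA, ], coords[iC, ])
  sweep(coords, 2, coords[iCA, ]) %*% F
}

#' Construct a RotamerLibrary from per-rotamer Cartesian conformers
#'
#' Conformer coordinates are re-expressed in the canonical local frame and
#' kept verbatim (stereoisomeric differences between conformers survive);
#' mobile dihedrals are measured per conformer.
#'
#' @param name library name (distinct from the residue name, so several
#'   libraries can serve the same residue type).
#' @param resname residue name (3-4 characters).
#' @param atom_names,elements character vectors, one entry per atom.
#' @param coords rotamer x atom x 3 array (Angstrom).
#' @param dihedral_defs list of atom-name quadruplets defining the mobile
#'   dihedrals, ordered from proximal to distal; may be empty.
#' @param spin_atoms,spin_weights spin-bearing atoms and their fractional
#'   spin populations (normalized internally).
#' @param weights per-rotamer weights (normalized internally); default uniform.
#' @param dihedral_sigmas per-dihedral (or rotamer x dihedral) standard
#'   deviations in degrees for off-rotamer sampling; NULL for the 35 degree
#'   default at sampling time.
#' @return a `RotamerLibrary`.
#' @export
new_rotamer_library <- function(name, resname, atom_names, elements, coords,
                                dihedral_defs, spin_atoms, spin_weights,
                                weights = NULL, dihedral_sigmas = NULL,
                                .canonical = FALSE, .dihedrals = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a rotamer x atom x 3 array", call. = FALSE)
  n_rot <- dim(coords)[1]; n_atom <- dim(coords)[2]
  stopifnot(length(atom_names) == n_atom, length(elements) == n_atom)
  quads <- lapply(dihedral_defs, function(q) {
    idx <- match(q, atom_names)
    if (anyNA(idx))
      stop("unknown atom in dihedral_defs: ", paste(q[is.na(idx)], collapse = ","),
           call. = FALSE)
    idx
  })
  sidx <- match(spin_atoms, atom_names)
  if (anyNA(sidx))
    stop("unknown spin atom: ", paste(spin_atoms[is.na(sidx)], collapse = ","),
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / n_rot, n_rot)
  if (length(weights) != n_rot || any(weights < 0) || sum(weights) <= 0)
    stop("invalid weights", call. = FALSE)
  weights <- weights / sum(weights)
  spin_weights <- spin_weights / sum(spin_weights)

  iN <- match("N", atom_names); iCA <- match("CA", atom_names)
  iC <- match("C", atom_names)
  if (anyNA(c(iN, iCA, iC)))
    stop("library invalid: backbone N/CA/C required", call. = FALSE)
  if (!.canonical)  # archives store canonical-frame coords: keep them bitwise
    for (r in seq_len(n_rot))
      coords[r, , ] <- to_local_frame(coords[r, , , drop = TRUE], iN, iCA, iC)

  bonds <- infer_bonds(coords[1, , , drop = TRUE], elements)
  adj <- adjacency_list(bonds, n_atom)
  ic <- ic_table(atom_names, adj, quads)
  template_ic <- measure_ic(coords[1, , , drop = TRUE], ic)
  downstream <- lapply(quads, function(q) downstream_atoms(adj, q[2], q[3]))

  if (is.null(.dihedrals)) {
    dihedrals <- matrix(0, n_rot, length(quads))
    for (r in seq_len(n_rot))
      for (k in seq_along(quads)) {
        q <- quads[[k]]
        dihedrals[r, k] <- measure_dihedral(coords[r, q[1], ], coords[r, q[2], ],
                                            coords[r, q[3], ], coords[r, q[4], ])
      }
  } else dihedrals <- .dihedrals

  structure(list(
    name = name, resname = resname, atom_names = atom_names,
    elements = elements, coords = coords, dihedral_defs = dihedral_defs,
    dihedral_quads = quads, downstream = downstream, dihedrals = dihedrals,
    weights = weights, dihedral_sigmas = dihedral_sigmas,
    spin_atoms = spin_atoms, spin_weights = spin_weights, spin_idx = sidx,
    ic = ic, template_ic = template_ic, adj = adj,
    format_version = "1.0"), class = "RotamerLibrary")
}

#' @export
print.RotamerLibrary <- function(x, ...) {
  cat(sprintf("<RotamerLibrary '%s' (%s): %d rotamers, %d atoms, %d mobile dihedral(s)>\n",
              x$name, x$resname, nrow(x$dihedrals), length(x$atom_names),
              length(x$dihedral_defs)))
  invisible(x)
}

#' Build Cartesian coordinates from the library's internal-coordinate template
#'
#' Bond lengths and angles come from the template (first conformer); the
#' mobile dihedrals are set to `dihedral_values`. Output is in the canonical
#' local frame. Deterministic: equal inputs give bitwise-equal output.
#'
#' @param library a `RotamerLibrary`.
#' @param dihedral_values numeric, one value (degrees) per mobile dihedral.
#' @return atom x 3 coordinate matrix.
#' @export
build_coords_from_internal <- function(library, dihedral_values) {
  if (length(dihedral_values) != length(library$dihedral_quads))
    stop("need one dihedral value per mobile dihedral", call. = FALSE)
  ic <- library$ic; tic <- library$template_ic
  n <- length(library$atom_names)
  dih <- tic$dihedral
  for (k in seq_along(library$dihedral_quads)) {
    q <- library$dihedral_quads[[k]]
    # the IC entry for q4 is defined against (q3, q2, q1): its dihedral IS
    # the mobile dihedral (measured q1-q2-q3-q4)
    dih[q[4]] <- dihedral_values[k]
  }
  co <- matrix(NA_real_, n, 3)
  iN <- ic$roots[1]; iCA <- ic$roots[2]; iC <- ic$roots[3]
  rt <- tic$root
  a <- rt$a_NCAC * pi / 180
  co[iCA, ] <- c(0, 0, 0)
  co[iN, ] <- c(rt$b_NCA * cos(a / 2), rt$b_NCA * sin(a / 2), 0)
  co[iC, ] <- c(rt$b_CAC * cos(a / 2), -rt$b_CAC * sin(a / 2), 0)
  for (i in ic$order[-(1:3)]) {
    r <- ic$refs[i, ]
    co[i, ] <- nerf_place(co[r[3], ], co[r[2], ], co[r[1], ],
                          tic$bond[i], tic$angle[i], dih[i])
  }
  # dependent dihedrals (siblings sharing a rotated reference) were measured
  # relative to the template; re-express in the canonical frame
  to_local_frame(co, iN, iCA, iC)
}

#' Validate a rotamer library
#'
#' Checks weight normalization, name resolution, dihedral ranges and bond
#' connectivity of the mobile-dihedral quadruplets.
#'
#' @param lib a `RotamerLibrary` (or a list with the same fields).
#' @return character vector of failure messages (empty when valid).
#' @export
validate_library <- function(lib) {
  fails <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) fails <<- c(fails, msg)
  w <- lib$weights
  chk(all(w >= 0) && abs(sum(w) - 1) < 1e-9, "weights must be >= 0 and sum to 1")
  sw <- lib$spin_weights
  chk(all(sw >= 0) && abs(sum(sw) - 1) < 1e-9,
      "spin_weights must be >= 0 and sum to 1")
  chk(all(lib$spin_atoms %in% lib$atom_names), "spin atom not in atom names")
  for (q in lib$dihedral_defs)
    chk(all(q %in% lib$atom_names),
        paste0("dihedral quadruplet names unknown atom: ",
               paste(setdiff(q, lib$atom_names), collapse = ",")))
  chk(all(is.finite(lib$coords)), "coordinates contain NaN")
  chk(all(is.finite(lib$dihedrals)) &&
        all(lib$dihedrals > -180 - 1e-9 & lib$dihedrals <= 180 + 1e-9),
      "dihedrals must be finite and in (-180, 180]")
  # quadruplet atoms must be consecutively bonded (1.9 A heavy / 1.2 A H rule)
  if (length(lib$dihedral_quads) && !is.null(lib$adj)) {
    for (k in seq_along(lib$dihedral_quads)) {
      q <- lib$dihedral_quads[[k]]
      if (all(q %in% seq_along(lib$atom_names))) {
        conn <- all(vapply(1:3, function(i) q[i + 1] %in% lib$adj[[q[i]]], TRUE))
        chk(conn, sprintf("dihedral %d atoms are not a bonded chain", k))
      }
    }
  }
  fails
}
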