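# A multistate StructureModel holding the toy library's conformers.
toy_multistate <- function(lib = toy_lib) {
  atoms <- data.frame(serial = seq_along(lib$atom_names), name = lib$atom_names,
                      element = lib$elements, resname = lib$resname,
                      resnum = 1L, chain = "A", occ = 1, b = 0,
                      stringsAsFactors = FALSE)
  spinlabelr:::new_structure_model(
    atoms, lapply(seq_len(dim(lib$coords)[1]), function(r) lib$coords[r, , ]),
    "toy-conformers")
}

test_that("create_library: Boltzmann weights, degenerate counts, errors", {
  ms <- toy_multistate()
  kT <- 0.593
  lib <- create_library("T1", ms, toy_lib$dihedral_defs, c("N1", "O1"),
                        c(0.5, 0.5), energies = c(0, kT * log(2), kT * log(4)))
  expect_equal(lib$weights, c(4, 2, 1) / 7, tolerance = 1e-12)
  # weight derivation is invariant to a constant energy shift
  lib_s <- create_library("T1", ms, toy_lib$dihedral_defs, c("N1", "O1"),
                          c(0.5, 0.5),
                          energies = 13 + c(0, kT * log(2), kT * log(4)))
  expect_equal(lib_s$weights, lib$weights)

  # single-model input stays sampling-capable
  one <- spinlabelr:::new_structure_model(ms$atoms, ms$coords[1], "one")
  lib1 <- create_library("T2", one, toy_lib$dihedral_defs, c("N1", "O1"),
                         c(0.5, 0.5))
  expect_equal(nrow(lib1$dihedrals), 1)
  sm <- sample_off_rotamers(lib1, 20, seed = 2)
  expect_equal(nrow(sm$dihedrals), 20)

  # no rotatable dihedrals (TOAC-like) is allowed
  lib0 <- create_library("T3", ms, list(), c("N1", "O1"), c(0.5, 0.5))
  expect_equal(ncol(lib0$dihedrals), 0)

  expect_error(create_library("T", ms, toy_lib$dihedral_defs, c("N1", "O1"),
                              c(0.5, 0.5), weights = c(1, 1, 1),
                              energies = c(0, 0, 0)),
               "at most one")
  expect_error(create_library("T", ms, list(c("N", "CA", "CB", "QQ")),
                              c("N1", "O1"), c(0.5, 0.5)),
               "unknown atom.*QQ")
  expect_error(create_library("T", ms, toy_lib$dihedral_defs, c("ZZ"), 1),
               "unknown spin atom")
})

test_that("multistate PDB ingestion rejects topology mismatches", {
  lib <- toy_lib
  block <- function(model, n_atoms) {
    c(sprintf("MODEL     %4d", model),
      vapply(seq_len(n_atoms), function(i)
        pdb_line(i, lib$atom_names[i], "TYL", "A", 1,
                 lib$coords[model, i, 1], lib$coords[model, i, 2],
                 lib$coords[model, i, 3], elem = lib$elements[i]), ""),
      "ENDMDL")
  }
  txt <- paste(c(block(1, 9), block(2, 8), "END"), collapse = "\n")
  expect_error(read_pdb(txt), "topology")
})

test_that("save/load round trip is bitwise; corruption is caught", {
  f <- withr::local_tempfile(fileext = ".rotlib.zip")
  save_library(toy_lib, f)
  lib2 <- load_library(f)
  expect_identical(lib2$coords, toy_lib$coords)
  expect_identical(lib2$weights, toy_lib$weights)
  expect_identical(lib2$dihedrals, toy_lib$dihedrals)
  expect_identical(lib2$atom_names, toy_lib$atom_names)
  expect_identical(lib2$spin_atoms, toy_lib$spin_atoms)
  expect_equal(lib2$dihedral_sigmas, toy_lib$dihedral_sigmas)

  # flip one byte inside the coords.f64 payload -> checksum failure.
  # the marker occurs in the manifest text, the local file header and the
  # central directory; the second-to-last occurrence is the local header,
  # immediately followed by the stored payload.
  raw <- readBin(f, "raw", file.size(f))
  marker <- charToRaw("coords.f64")
  hits <- integer()
  for (i in seq_len(length(raw) - length(marker))) {
    if (all(raw[i:(i + length(marker) - 1)] == marker)) hits <- c(hits, i)
  }
  off <- hits[length(hits) - 1] + length(marker) + 40  # inside the floats
  raw[off] <- as.raw(bitwXor(as.integer(raw[off]), 255L))
  f2 <- withr::local_tempfile(fileext = ".zip")
  writeBin(raw, f2)
  expect_error(suppressWarnings(load_library(f2)), "corrupt")

  expect_error(load_library(withr::local_tempfile()), "no such archive")
})

test_that("unknown format versions are rejected", {
  f <- withr::local_tempfile(fileext = ".zip")
  lib <- toy_lib
  lib$format_version <- "9.9"
  save_library(lib, f)
  expect_error(load_library(f), "format version")
})

test_that("create -> save -> load -> attach reproduces the source conformers", {
  # conformers written to a real multistate PDB, read back, made into a
  # library, archived, reloaded, attached to the backbone they came from
  ms <- toy_multistate()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ms, pdb)
  ms2 <- read_pdb(pdb)
  lib <- create_library("RT", ms2, toy_lib$dihedral_defs, c("N1", "O1"),
                        c(0.5, 0.5), weights = toy_lib$weights)
  arch <- withr::local_tempfile(fileext = ".rotlib.zip")
  save_library(lib, arch)
  lib2 <- load_library(arch)

  site <- spinlabelr:::new_structure_model(
    ms$atoms, ms$coords[1], "site")  # conformer 1's own backbone
  lab <- attach_label(lib2, site, "A", 1, eval_clash = FALSE)
  for (r in 1:3)
    expect_lt(max(abs(lab$coords[r, , ] - toy_lib$coords[r, , ])), 2e-3)
})

test_that("library name is independent of residue name", {
  ms <- toy_multistate()
  libA <- create_library("VARIANT-A", ms, toy_lib$dihedral_defs,
                         c("N1", "O1"), c(0.5, 0.5))
  libB <- create_library("VARIANT-B", ms, toy_lib$dihedral_defs,
                         c("N1", "O1"), c(0.5, 0.5),
                         weights = c(0.1, 0.1, 0.8))
  expect_identical(libA$resname, libB$resname)
  la <- attach_label(libA, helix10, "A", 4, eval_clash = FALSE)
  lb <- attach_label(libB, helix10, "A", 4, eval_clash = FALSE)
  expect_identical(la$resname, lb$resname)
  expect_false(isTRUE(all.equal(la$weights, lb$weights)))
})

test_that("validate_library reports specific failures", {
  expect_length(validate_library(toy_lib), 0)
  broken <- toy_lib
  broken$weights <- c(0.5, 0.3, 0.1)  # sums to 0.9
  expect_match(validate_library(broken), "sum to 1", all = FALSE)
  named <- toy_lib
  named$dihedral_defs[[1]] <- c("N", "CA", "CB", "NOPE")
  expect_match(validate_library(named), "unknown atom", all = FALSE)
  nan <- toy_lib
  nan$coords[1, 1, 1] <- NaN
  expect_match(validate_library(nan), "NaN", all = FALSE)
})
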