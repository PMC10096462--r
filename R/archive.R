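# Portable rotamer-library archives (.rotlib.zip): a ZIP container holding
# manifest.json plus one raw little-endian float64 file per array
# (coords.f64, weights.f64, dihedrals.f64), row-major, shapes and checksums
# in the manifest. The writer emits stored (uncompressed) ZIP entries in
# pure R; reading goes through utils::unzip's internal decoder, so no
# external tools are needed on either side.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      poly <- -306674912L  # 0xEDB88320 as signed 32-bit
      t <- integer(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L))
               else bitwShiftR(c, 1L)
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(raw_bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(raw_bytes)
  for (x in b)
    c <- bitwXor(tab[bitwAnd(bitwXor(c, x), 255L) + 1L], bitwShiftR(c, 8L))
  bitwXor(c, -1L)
}

crc32_hex <- function(raw_bytes) {
  v <- crc32(raw_bytes)
  paste(format(as.hexmode(bitwAnd(bitwShiftR(v, 16L), 65535L)), width = 4),
        format(as.hexmode(bitwAnd(v, 65535L)), width = 4), sep = "")
}

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  x <- as.numeric(x)
  if (x >= 2^31) x <- x - 2^32
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

# Minimal ZIP writer, store method only. files: named list of raw vectors.
write_zip <- function(path, files) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- raw(0)
  pos <- 0
  for (nm in names(files)) {
    data <- files[[nm]]
    crc <- crc32(data)
    name_raw <- charToRaw(nm)
    local_hdr <- c(u32(0x04034b50), u16(20), u16(0), u16(0), u16(0), u16(0x21),
                   u32(crc), u32(length(data)), u32(length(data)),
                   u16(length(name_raw)), u16(0))
    writeBin(c(local_hdr, name_raw, data), con)
    central <- c(central,
                 u32(0x02014b50), u16(20), u16(20), u16(0), u16(0), u16(0),
                 u16(0x21), u32(crc), u32(length(data)), u32(length(data)),
                 u16(length(name_raw)), u16(0), u16(0), u16(0), u16(0),
                 u32(0), u32(pos), name_raw)
    pos <- pos + length(local_hdr) + length(name_raw) + length(data)
    offsets <- c(offsets, pos)
  }
  cd_start <- pos
  writeBin(central, con)
  writeBin(c(u32(0x06054b50), u16(0), u16(0), u16(length(files)),
             u16(length(files)), u32(length(central)), u32(cd_start), u16(0)),
           con)
  invisible(path)
}

doubles_to_raw <- function(x) writeBin(as.numeric(x), raw(), size = 8,
                                       endian = "little")
raw_to_doubles <- function(r) readBin(r, "double", n = length(r) / 8,
                                      size = 8, endian = "little")

# Row-major flattening so the on-disk layout is language-neutral.
flatten_rowmajor <- function(a) {
  if (is.null(dim(a))) return(as.numeric(a))
  as.numeric(aperm(a, rev(seq_along(dim(a)))))
}
unflatten_rowmajor <- function(v, shape) {
  if (length(shape) <= 1) return(as.numeric(v))
  aperm(array(v, rev(shape)), rev(seq_along(shape)))
}

#' Save a rotamer library to a portable archive
#'
#' @param lib a `RotamerLibrary`.
#' @param path output path (conventionally `<name>.rotlib.zip`).
#' @return invisibly, the path.
#' @export
save_library <- function(lib, path) {
  shapes <- list(coords = dim(lib$coords),
                 weights = length(lib$weights),
                 dihedrals = dim(lib$dihedrals))
  arrays <- list(
    "coords.f64" = doubles_to_raw(flatten_rowmajor(lib$coords)),
    "weights.f64" = doubles_to_raw(lib$weights),
    "dihedrals.f64" = doubles_to_raw(flatten_rowmajor(lib$dihedrals)))
  sig <- lib$dihedral_sigmas
  manifest <- list(
    format_version = lib$format_version,
    name = lib$name, resname = lib$resname,
    atom_names = lib$atom_names, elements = lib$elements,
    dihedral_defs = lapply(lib$dihedral_defs, as.character),
    spin_atoms = lib$spin_atoms, spin_weights = lib$spin_weights,
    dihedral_sigmas = if (is.null(sig)) NULL else as.numeric(sig),
    dihedral_sigmas_shape = if (is.matrix(sig)) dim(sig) else
      if (is.null(sig)) NULL else length(sig),
    downstream = lapply(lib$downstream, function(d) lib$atom_names[d]),
    shapes = shapes,
    checksum_algorithm = "crc32",
    checksums = lapply(arrays, crc32_hex))
  files <- c(list("manifest.json" = charToRaw(
    jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, null = "null"))),
    arrays)
  write_zip(path, files)
}

#' Load a rotamer library from a portable archive
#'
#' Verifies the per-array checksums and the format version, then rebuilds
#' the full `RotamerLibrary` (bond graph and internal-coordinate template
#' are rederived from the stored coordinates).
#'
#' @param path archive path.
#' @return a `RotamerLibrary`.
#' @export
load_library <- function(path) {
  if (!file.exists(path)) stop("no such archive: ", path, call. = FALSE)
  tmp <- tempfile("rotlib")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  got <- try(utils::unzip(path, exdir = tmp), silent = TRUE)
  if (inherits(got, "try-error") ||
      !file.exists(file.path(tmp, "manifest.json")))
    stop("corrupt archive: not a readable rotlib ZIP", call. = FALSE)
  man <- tryCatch(
    jsonlite::fromJSON(file.path(tmp, "manifest.json"), simplifyVector = TRUE),
    error = function(e)
      stop("corrupt archive: unreadable manifest (", conditionMessage(e), ")",
           call. = FALSE))
  if (!identical(man$format_version, "1.0"))
    stop("unknown rotlib format version: ", man$format_version, call. = FALSE)
  read_arr <- function(fname, shape) {
    p <- file.path(tmp, fname)
    if (!file.exists(p)) stop("corrupt archive: missing ", fname, call. = FALSE)
    r <- readBin(p, "raw", n = file.size(p))
    if (!identical(crc32_hex(r), man$checksums[[fname]]))
      stop("corrupt archive: checksum mismatch in ", fname, call. = FALSE)
    unflatten_rowmajor(raw_to_doubles(r), shape)
  }
  coords <- read_arr("coords.f64", man$shapes$coords)
  weights <- read_arr("weights.f64", man$shapes$weights)
  dihedrals <- read_arr("dihedrals.f64", man$shapes$dihedrals)
  sig <- man$dihedral_sigmas
  if (!is.null(sig) && !is.null(man$dihedral_sigmas_shape) &&
      length(man$dihedral_sigmas_shape) == 2)
    sig <- matrix(sig, man$dihedral_sigmas_shape[1],
                  man$dihedral_sigmas_shape[2], byrow = TRUE)
  defs <- man$dihedral_defs
  if (is.matrix(defs)) defs <- lapply(seq_len(nrow(defs)), function(i) defs[i, ])
  if (!is.list(defs)) defs <- as.list(defs)
  if (length(man$shapes$dihedrals) < 2)
    dihedrals <- matrix(dihedrals, nrow = man$shapes$coords[1])
  new_rotamer_library(man$name, man$resname, man$atom_names, man$elements,
                      coords, defs, man$spin_atoms, man$spin_weights,
                      weights = weights, dihedral_sigmas = sig,
                      .canonical = TRUE, .dihedrals = dihedrals)
}

#' Create a rotamer library from a multistate conformer structure
#'
#' Each model of the input becomes one rotamer; coordinates are re-expressed
#' in the canonical local frame but otherwise kept verbatim, so any
#' stereoisomeric heterogeneity among the conformers (e.g. maleimide
#' diastereomers) is retained. Weights come from `weights`, or from
#' `energies` via Boltzmann factors at `kT`, or are uniform. Single-model
#' input and empty `dihedral_defs` (TOAC-like labels) are both allowed.
#'
#' @param name library name.
#' @param multistate a `StructureModel` whose models are the conformers.
#' @param dihedral_defs list of mobile-dihedral atom-name quadruplets.
#' @param spin_atoms,spin_weights spin-density atoms and fractions.
#' @param weights optional per-conformer weights (exclusive with energies).
#' @param dihedral_sigmas optional off-rotamer sigmas (degrees).
#' @param energies optional per-conformer energies in kcal/mol.
#' @param kT Boltzmann factor for energies -> weights (default 0.593).
#' @return a `RotamerLibrary`.
#' @export
create_library <- function(name, multistate, dihedral_defs, spin_atoms,
                           spin_weights, weights = NULL,
                           dihedral_sigmas = NULL, energies = NULL,
                           kT = 0.593) {
  if (!is.null(weights) && !is.null(energies))
    stop("provide at most one of weights/energies", call. = FALSE)
  nm <- n_models(multistate)
  if (!is.null(energies)) {
    if (length(energies) != nm)
      stop("need one energy per conformer", call. = FALSE)
    weights <- reweight(rep(1, nm), energies, kT)
  }
  a <- multistate$atoms
  resname <- a$resname[1]
  n_atom <- nrow(a)
  coords <- array(0, c(nm, n_atom, 3))
  for (m in seq_len(nm)) coords[m, , ] <- multistate$coords[[m]]
  new_rotamer_library(name, resname, a$name, a$element, coords,
                      dihedral_defs, spin_atoms, spin_weights,
                      weights = weights, dihedral_sigmas = dihedral_sigmas)
}
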