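# PDB reading/writing, atom selection, and site mutation.
#
# A StructureModel is a light-weight container: one atom table shared by all
# models plus a list of coordinate frames. Waters are carried in the table but
# are excluded automatically from every clash environment downstream.

new_structure_model <- function(atoms, coords, source = "") {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1)
  coords <- lapply(coords, function(m) {
    if (!is.matrix(m) || nrow(m) != nrow(atoms) || ncol(m) != 3)
      stop("all models must share one topology (atom count mismatch)",
           call. = FALSE)
    if (!all(is.finite(m))) stop("non-finite coordinates", call. = FALSE)
    dimnames(m) <- NULL
    m
  })
  structure(list(atoms = atoms, coords = coords, source = source),
            class = "StructureModel")
}

n_models <- function(s) length(s$coords)
n_atoms <- function(s) nrow(s$atoms)

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("<StructureModel '%s': %d atoms, %d model(s), %d residue(s)>\n",
              x$source, n_atoms(x), n_models(x),
              nrow(unique(x$atoms[, c("chain", "resnum")]))))
  invisible(x)
}

element_from_name <- function(name) {
  # PDB atom names lead with the element; digits and primes are decoration
  s <- gsub("[0-9' ]", "", name)
  two <- c("BR", "CL", "CU", "GD", "FE", "ZN", "MG", "MN", "NA", "SE")
  if (toupper(substr(s, 1, 2)) %in% two) {
    sub <- substr(s, 1, 2)
    paste0(substr(sub, 1, 1), tolower(substr(sub, 2, 2)))
  } else substr(s, 1, 1)
}

#' Read a PDB file or text into a StructureModel
#'
#' Parses ATOM and HETATM records, honouring MODEL/ENDMDL blocks (all models
#' must share one topology). Alternate-location indicators other than blank
#' or 'A' are skipped so the clash environment is a single conformer.
#' Insertion codes are not supported.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @return a `StructureModel`.
#' @export
read_pdb <- function(input) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input, warn = FALSE)
    src <- basename(input)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    src <- "text"
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- integer(length(lines))
  cur <- 0L; seen_model <- FALSE
  starts <- grep("^MODEL", lines)
  if (length(starts)) {
    ids <- cumsum(grepl("^MODEL", lines))
    model_id <- ids
    seen_model <- TRUE
  } else model_id[] <- 1L
  model_id[model_id == 0L] <- 1L

  keep <- which(is_atom)
  if (!length(keep)) stop("empty structure: no ATOM/HETATM records", call. = FALSE)
  fx <- function(l, a, b) substr(l, a, b)
  parse_num <- function(txt, what, lineno) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(v) & nzchar(trimws(txt)))
    if (any(!is.finite(v)))
      stop(sprintf("malformed %s field at line %d", what,
                   lineno[which(!is.finite(v))[1]]), call. = FALSE)
    v
  }
  l <- lines[keep]
  altloc <- fx(l, 17, 17)
  ok_alt <- altloc %in% c(" ", "", "A")
  l <- l[ok_alt]; keep <- keep[ok_alt]
  if (!length(l)) stop("empty structure: no usable ATOM/HETATM records", call. = FALSE)
  icode <- trimws(fx(l, 27, 27))
  if (any(nzchar(icode)))
    stop(sprintf("insertion codes unsupported (line %d)",
                 keep[which(nzchar(icode))[1]]), call. = FALSE)

  serial <- parse_num(fx(l, 7, 11), "serial", keep)
  name <- trimws(fx(l, 13, 16))
  resname <- trimws(fx(l, 18, 21))
  chain <- fx(l, 22, 22)
  resnum <- parse_num(fx(l, 23, 26), "residue number", keep)
  x <- parse_num(fx(l, 31, 38), "coordinate", keep)
  y <- parse_num(fx(l, 39, 46), "coordinate", keep)
  z <- parse_num(fx(l, 47, 54), "coordinate", keep)
  occ <- suppressWarnings(as.numeric(fx(l, 55, 60))); occ[!is.finite(occ)] <- 1
  b <- suppressWarnings(as.numeric(fx(l, 61, 66))); b[!is.finite(b)] <- 0
  elem <- trimws(fx(l, 77, 78))
  miss <- !nzchar(elem)
  if (any(miss)) elem[miss] <- vapply(name[miss], element_from_name, "")
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))

  mid <- model_id[keep]
  um <- unique(mid)
  at1 <- mid == um[1]
  atoms <- data.frame(serial = serial[at1], name = name[at1],
                      element = elem[at1], resname = resname[at1],
                      resnum = as.integer(resnum[at1]), chain = chain[at1],
                      occ = occ[at1], b = b[at1], stringsAsFactors = FALSE)
  coords <- lapply(um, function(m) {
    i <- mid == m
    if (sum(i) != nrow(atoms))
      stop("all models must share one topology (atom count mismatch)",
           call. = FALSE)
    cbind(x[i], y[i], z[i])
  })
  new_structure_model(atoms, coords, src)
}

format_atom_name <- function(name, element) {
  # names shorter than 4 chars start in column 14 unless a 2-char element
  if (nchar(name) >= 4 || nchar(element) >= 2) sprintf("%-4s", name)
  else sprintf(" %-3s", name)
}

pdb_atom_line <- function(record, serial, name, resname, chain, resnum,
                          xyz, occ, b, element) {
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000, format_atom_name(name, element),
          resname, chain, resnum, xyz[1], xyz[2], xyz[3], occ, b,
          toupper(element))
}

structure_lines <- function(s, model) {
  a <- s$atoms; co <- s$coords[[model]]
  rec <- ifelse(a$resname %in% c("HOH", "WAT") |
                  !a$resname %in% c(AMINO_ACIDS, "TYL"), "HETATM", "ATOM")
  # residues known as polymer get ATOM; everything else HETATM
  vapply(seq_len(nrow(a)), function(i)
    pdb_atom_line(rec[i], a$serial[i], a$name[i], a$resname[i], a$chain[i],
                  a$resnum[i], co[i, ], a$occ[i], a$b[i], a$element[i]), "")
}

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Write a StructureModel to PDB
#'
#' @param s a `StructureModel`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(s, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  if (n_models(s) == 1) {
    writeLines(structure_lines(s, 1), con)
  } else {
    for (m in seq_len(n_models(s))) {
      writeLines(sprintf("MODEL     %4d", m), con)
      writeLines(structure_lines(s, m), con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

# ---- selection grammar ------------------------------------------------------

new_atom_subset <- function(structure, idx) {
  idx <- sort(unique(as.integer(idx)))
  stopifnot(all(idx >= 1), all(idx <= n_atoms(structure)))
  structure(list(structure = structure, idx = idx), class = "AtomSubset")
}

SELECT_KEYWORDS <- c("chain", "resnum", "name", "element", "not", "water",
                     "and", "or", "(", ")")

tokenize_query <- function(query) {
  q <- gsub("([()])", " \\1 ", query)
  toks <- strsplit(trimws(q), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Select atoms with a small query grammar
#'
#' Supported primitives: `chain <id>`, `resnum <n|n-m> ...`,
#' `name <list>`, `element <list>`, `not water`; combinable with
#' `and`, `or` and parentheses.
#'
#' @param structure a `StructureModel`.
#' @param query query string.
#' @return an `AtomSubset` (sorted unique indices into the atom table).
#' @export
select_atoms <- function(structure, query) {
  toks <- tokenize_query(query)
  if (!length(toks)) stop("query-syntax error at position 1: empty query",
                          call. = FALSE)
  a <- structure$atoms
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  syntax_err <- function(msg)
    stop(sprintf("query-syntax error at token %d ('%s'): %s", pos,
                 ifelse(is.na(peek()), "<end>", peek()), msg), call. = FALSE)

  values_until_keyword <- function() {
    vals <- character()
    while (!is.na(peek()) && !(peek() %in% SELECT_KEYWORDS)) vals <- c(vals, advance())
    if (!length(vals)) syntax_err("expected one or more values")
    vals
  }
  parse_primary <- function() {
    t <- peek()
    if (is.na(t)) syntax_err("unexpected end of query")
    if (t == "(") {
      advance()
      m <- parse_expr()
      if (!identical(peek(), ")")) syntax_err("expected ')'")
      advance()
      return(m)
    }
    if (t == "not") {
      advance()
      if (!identical(peek(), "water")) syntax_err("'not' supports only 'not water'")
      advance()
      return(!(a$resname %in% c("HOH", "WAT")))
    }
    if (t == "chain") { advance(); return(a$chain %in% values_until_keyword()) }
    if (t == "name") { advance(); return(a$name %in% values_until_keyword()) }
    if (t == "element") { advance(); return(a$element %in% values_until_keyword()) }
    if (t == "resnum") {
      advance()
      vals <- values_until_keyword()
      m <- rep(FALSE, nrow(a))
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
          parts <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
          m <- m | (a$resnum >= as.integer(parts[2]) &
                    a$resnum <= as.integer(parts[3]))
        } else if (grepl("^-?[0-9]+$", v)) {
          m <- m | a$resnum == as.integer(v)
        } else syntax_err(sprintf("bad resnum value '%s'", v))
      }
      return(m)
    }
    syntax_err("expected a selection primitive")
  }
  parse_term <- function() {
    m <- parse_primary()
    while (identical(peek(), "and")) { advance(); m <- m & parse_primary() }
    m
  }
  parse_expr <- function() {
    m <- parse_term()
    while (identical(peek(), "or")) { advance(); m <- m | parse_term() }
    m
  }
  mask <- parse_expr()
  if (!is.na(peek())) syntax_err("trailing tokens")
  new_atom_subset(structure, which(mask))
}

residue_indices <- function(structure, chain, resnum) {
  which(structure$atoms$chain == chain & structure$atoms$resnum == resnum)
}

backbone_indices <- function(structure, chain, resnum,
                             names = c("N", "CA", "C")) {
  idx <- residue_indices(structure, chain, resnum)
  out <- vapply(names, function(nm) {
    i <- idx[structure$atoms$name[idx] == nm]
    if (!length(i)) NA_integer_ else i[1]
  }, 1L)
  if (anyNA(out))
    stop(sprintf("incomplete backbone at %s%d: missing %s", chain, resnum,
                 paste(names[is.na(out)], collapse = ",")), call. = FALSE)
  out
}

#' Replace a residue's side chain with one rotamer of an attached ensemble
#'
#' Backbone atoms N, CA, C, O keep their native coordinates; all other atoms
#' of the residue are replaced by the chosen rotamer's side-chain atoms and
#' the residue is renamed to the ensemble's residue name. Operates on (and
#' returns) a single-model structure.
#'
#' @param structure a `StructureModel`.
#' @param chain,resnum the site.
#' @param ensemble a `RotamerEnsemble`/`SpinLabel` already attached at the site.
#' @param rotamer_index which rotamer to graft in.
#' @return a new `StructureModel` with one model.
#' @export
mutate_site <- function(structure, chain, resnum, ensemble, rotamer_index) {
  if (rotamer_index < 1 || rotamer_index > nrow(ensemble$dihedrals) ||
      rotamer_index != round(rotamer_index))
    stop("rotamer_index out of range", call. = FALSE)
  backbone_indices(structure, chain, resnum)  # errors if incomplete
  a <- structure$atoms
  co <- structure$coords[[1]]
  res <- residue_indices(structure, chain, resnum)
  keep_bb <- res[a$name[res] %in% c("N", "CA", "C", "O")]
  drop <- setdiff(res, keep_bb)
  sc <- which(!(ensemble$atom_names %in% c("N", "CA", "C", "O")))
  ins_atoms <- data.frame(serial = 0L, name = ensemble$atom_names[sc],
                          element = ensemble$elements[sc],
                          resname = ensemble$resname, resnum = as.integer(resnum),
                          chain = chain, occ = 1, b = 0,
                          stringsAsFactors = FALSE)
  ins_co <- ensemble$coords[rotamer_index, sc, , drop = TRUE]
  if (is.null(dim(ins_co))) ins_co <- matrix(ins_co, ncol = 3)
  keep <- setdiff(seq_len(nrow(a)), drop)
  # rename the kept backbone of the site
  a2 <- a[keep, , drop = FALSE]
  a2$resname[keep %in% keep_bb] <- ensemble$resname
  co2 <- co[keep, , drop = FALSE]
  at_pos <- max(match(keep_bb, keep))
  atoms_out <- rbind(a2[seq_len(at_pos), , drop = FALSE], ins_atoms,
                     if (at_pos < nrow(a2)) a2[(at_pos + 1):nrow(a2), , drop = FALSE])
  coords_out <- rbind(co2[seq_len(at_pos), , drop = FALSE], ins_co,
                      if (at_pos < nrow(co2)) co2[(at_pos + 1):nrow(co2), , drop = FALSE])
  atoms_out$serial <- seq_len(nrow(atoms_out))
  rownames(atoms_out) <- NULL
  new_structure_model(atoms_out, list(coords_out), structure$source)
}

#' Write a protein plus attached label ensembles to a PDB file
#'
#' The output contains (a) the protein verbatim, (b) for each label one MODEL
#' block per rotamer with every atom's occupancy set to that rotamer's weight,
#' and (c) HETATM pseudo-atoms (name "NEN", residue "SCN") at each rotamer's
#' spin center, occupancy again the rotamer weight.
#'
#' @param path output path.
#' @param protein a `StructureModel` (or NULL for labels only).
#' @param labels list of `SpinLabel` objects (possibly empty).
#' @return invisibly, the path.
#' @export
write_ensemble_pdb <- function(path, protein, labels = list()) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  if (!is.null(protein)) {
    if (n_models(protein) == 1) writeLines(structure_lines(protein, 1), con)
    else for (m in seq_len(n_models(protein))) {
      writeLines(sprintf("MODEL     %4d", m), con)
      writeLines(structure_lines(protein, m), con)
      writeLines("ENDMDL", con)
    }
  }
  for (lab in labels) {
    nr <- length(lab$weights)
    for (r in seq_len(nr)) {
      writeLines(sprintf("MODEL     %4d", r), con)
      for (i in seq_along(lab$atom_names)) {
        writeLines(pdb_atom_line("ATOM", i, lab$atom_names[i], lab$resname,
                                 lab$site$chain, lab$site$resnum,
                                 lab$coords[r, i, ], lab$weights[r], 0,
                                 lab$elements[i]), con)
      }
      writeLines("ENDMDL", con)
    }
    sc <- spin_centers(lab)
    for (r in seq_len(nr)) {
      writeLines(pdb_atom_line("HETATM", r, "NEN", "SCN", lab$site$chain,
                               lab$site$resnum, sc[r, ], lab$weights[r], 0,
                               "N"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}
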