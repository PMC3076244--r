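# SDF / MOL V2000 reading and writing. Explicit hydrogen atoms in a record
# are folded into the neighbor's hydrogen count so the in-memory graph stays
# heavy-atom only; bond order 4 is read as aromatic, and Kekule rings are
# aromatized with the same perception as the SMILES reader.

#' Read molecules from an SDF/MOL V2000 file
#'
#' Records that fail to sanitize are skipped with a warning; the number of
#' skipped records is attached as attribute `n_skipped`.
#'
#' @param path path to an SDF or MOL file.
#' @return a list of `hm_mol`, names taken from each record title.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop_usage(paste("cannot read file:", path))
  lines <- readLines(path, warn = FALSE)
  # split into records on $$$$ (a lone MOL file is one record)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1) + 1L)
  mols <- list()
  skipped <- 0L
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    rec <- rec[trimws(rec) != "$$$$"]
    if (all(!nzchar(trimws(rec)))) next
    m <- tryCatch(parse_molblock(rec), error = function(e) e)
    if (inherits(m, "error")) {
      warning(sprintf("skipping SDF record %d: %s", r, conditionMessage(m)),
              call. = FALSE)
      skipped <- skipped + 1L
    } else {
      mols[[length(mols) + 1L]] <- m
    }
  }
  if (length(mols) == 0) stop_data("no parsable records in SDF file")
  names(mols) <- vapply(mols, function(m) m$name, character(1))
  attr(mols, "n_skipped") <- skipped
  mols
}

parse_molblock <- function(rec) {
  if (length(rec) < 4) stop_data("truncated record")
  title <- trimws(rec[1])
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) stop_data("bad counts line")
  if (length(rec) < 4 + na + nb) stop_data("truncated atom/bond block")
  atom_lines <- rec[5:(4 + na)]
  el <- trimws(substr(atom_lines, 32, 34))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  if (any(is.na(x) | is.na(y)) || any(!nzchar(el)))
    stop_data("bad atom block")
  b1 <- b2 <- integer(nb); bt <- integer(nb)
  if (nb > 0) {
    bond_lines <- rec[(5 + na):(4 + na + nb)]
    b1 <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
    b2 <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
    bt <- suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
    if (any(is.na(b1) | is.na(b2) | is.na(bt))) stop_data("bad bond block")
  }
  charge <- integer(na)
  for (ln in grep("^M  CHG", rec, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nent <- f[1]
    for (k in seq_len(nent)) {
      charge[f[2 * k]] <- f[2 * k + 1]
    }
  }
  order <- c("single", "double", "triple", "aromatic")[bt]
  if (any(is.na(order))) stop_data("unsupported bond type")

  # fold explicit hydrogens into neighbor H counts
  is_h <- el == "H"
  folded <- integer(na)
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- match(seq_len(na), keep)
    for (i in seq_len(nb)) {
      hi <- is_h[b1[i]]; hj <- is_h[b2[i]]
      if (hi && hj) stop_data("H-H bond unsupported")
      if (hi) folded[b2[i]] <- folded[b2[i]] + 1L
      if (hj) folded[b1[i]] <- folded[b1[i]] + 1L
    }
    kb <- !(is_h[b1] | is_h[b2])
    b1 <- remap[b1[kb]]; b2 <- remap[b2[kb]]; order <- order[kb]
    el <- el[keep]; x <- x[keep]; y <- y[keep]
    charge <- charge[keep]; folded <- folded[keep]
    na <- length(keep)
  }
  aromatic_in <- logical(na)
  if (length(order) > 0) {
    ar <- order == "aromatic"
    aromatic_in[c(b1[ar], b2[ar])] <- TRUE
  }
  atoms <- data.frame(element = el, charge = charge, hcount = 0L,
                      aromatic = aromatic_in, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b1, a2 = b2, order = order,
                      stringsAsFactors = FALSE)
  mol <- structure(list(atoms = atoms, bonds = bonds, name = title,
                        coords = cbind(x, y)), class = "hm_mol")
  mol <- perceive_rings(mol)
  mol$atoms$hcount <- implicit_hydrogens(mol, folded_h = folded)
  mol <- aromatize(mol)
  new_molecule(mol$atoms, mol$bonds, name = title, coords = cbind(x, y))
}

#' Write molecules to an SDF file
#'
#' V2000 dialect; aromatic bonds are written as bond type 4, charges as
#' `M  CHG` lines. Coordinates are taken from the molecule or generated
#' with the built-in 2D layout.
#'
#' @param mols a single `hm_mol` or a list of them.
#' @param path output path.
#' @param data optional data.frame of per-molecule data fields (one column
#'   per field, one row per molecule).
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, data = NULL) {
  if (inherits(mols, "hm_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    xy <- if (!is.null(mol$coords)) mol$coords else layout2d(mol)
    na <- n_atoms(mol); nb <- n_bonds(mol)
    writeLines(c(mol$name, "  svmheatmap", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
               con)
    for (a in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xy[a, 1], xy[a, 2], 0, mol$atoms$element[a]), con)
    }
    bt <- match(mol$bonds$order, c("single", "double", "triple", "aromatic"))
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$a1[b], mol$bonds$a2[b],
                         bt[b]), con)
    }
    chgd <- which(mol$atoms$charge != 0)
    if (length(chgd) > 0) {
      for (grp in split(chgd, ceiling(seq_along(chgd) / 8))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp,
                                         mol$atoms$charge[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    if (!is.null(data)) {
      for (field in names(data)) {
        writeLines(c(sprintf(">  <%s>", field), as.character(data[k, field]),
                     ""), con)
      }
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
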