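# SMILES reader for the organic subset plus bracket atoms. Supported:
# B C N O P S F Cl Br I (and aromatic b c n o p s), branches, ring closures
# (including %nn), bond symbols - = # : / \, disconnected parts via '.',
# bracket atoms with charge and explicit H count (isotopes and stereo marks
# are accepted and ignored). Inputs are expected to be pre-standardized;
# only default sanitization (ring perception, Hueckel aromatization of
# Kekule rings, implicit hydrogen assignment) is applied.

ORGANIC_TWO <- c("Cl", "Br")
ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecule
#'
#' @param smiles a single SMILES string.
#' @param name molecule title (defaults to the SMILES itself).
#' @return an `hm_mol` with perceived aromaticity, ring membership and
#'   per-atom hydrogen counts (hydrogens are atom attributes, not nodes).
#' @examples
#' m <- parse_smiles("c1ccccc1O")  # phenol
#' n_atoms(m); n_bonds(m)
#' @export
parse_smiles <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  s <- trimws(smiles)
  if (!nzchar(s)) stop_data("empty SMILES")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  np <- length(ch)

  el <- character(); chg <- integer(); hc <- integer(); arom <- logical()
  hexp <- logical()
  b1 <- integer(); b2 <- integer(); bord <- character()

  prev <- NA_integer_
  stack <- integer()
  pend <- NA_character_
  ring_open <- list()  # digit -> list(atom, bond)

  fail <- function(i, msg)
    stop_data(sprintf("SMILES parse error at position %d ('%s'): %s",
                      i, substr(s, i, i), msg))

  bond_order <- function(sym, a, b) {
    if (!is.na(sym)) {
      switch(sym, "-" = "single", "/" = "single", "\\" = "single",
             "=" = "double", "#" = "triple", ":" = "aromatic",
             fail(0, paste("bad bond symbol", sym)))
    } else if (arom[a] && arom[b]) "aromatic" else "single"
  }

  add_atom <- function(sym, aromatic, charge = 0L, h = NA_integer_) {
    el[length(el) + 1L] <<- sym
    chg[length(chg) + 1L] <<- charge
    hc[length(hc) + 1L] <<- if (is.na(h)) 0L else h
    hexp[length(hexp) + 1L] <<- !is.na(h)
    arom[length(arom) + 1L] <<- aromatic
    idx <- length(el)
    if (!is.na(prev)) {
      b1[length(b1) + 1L] <<- prev
      b2[length(b2) + 1L] <<- idx
      bord[length(bord) + 1L] <<- bond_order(pend, prev, idx)
    }
    pend <<- NA_character_
    prev <<- idx
    idx
  }

  close_ring <- function(d, i) {
    if (!is.null(ring_open[[d]])) {
      op <- ring_open[[d]]
      if (is.na(prev)) fail(i, "ring closure before any atom")
      sym <- if (!is.na(pend)) pend else op$bond
      b1[length(b1) + 1L] <<- op$atom
      b2[length(b2) + 1L] <<- prev
      bord[length(bord) + 1L] <<- bond_order(sym, op$atom, prev)
      ring_open[[d]] <<- NULL
      pend <<- NA_character_
    } else {
      if (is.na(prev)) fail(i, "ring opening before any atom")
      ring_open[[d]] <<- list(atom = prev, bond = pend)
      pend <<- NA_character_
    }
  }

  i <- 1L
  while (i <= np) {
    c1 <- ch[i]
    if (c1 == "(") {
      if (is.na(prev)) fail(i, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (c1 == ")") {
      if (length(stack) == 0) fail(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (c1 %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- c1
      i <- i + 1L
    } else if (c1 == ".") {
      prev <- NA_integer_
      pend <- NA_character_
      i <- i + 1L
    } else if (c1 == "%") {
      if (i + 2L > np || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L)))
        fail(i, "'%' needs two digits")
      close_ring(substr(s, i + 1L, i + 2L), i)
      i <- i + 3L
    } else if (grepl("[0-9]", c1)) {
      close_ring(c1, i)
      i <- i + 1L
    } else if (c1 == "[") {
      j <- which(ch == "]" & seq_along(ch) > i)[1]
      if (is.na(j)) fail(i, "unterminated bracket atom")
      body <- substr(s, i + 1L, j - 1L)
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Z][a-z]?|[bcnops])(@{1,2}|@TH[12])?(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0) fail(i, paste("bad bracket atom", body))
      sym <- m[3]
      aromatic <- sym %in% AROMATIC_ORGANIC
      if (aromatic) sym <- toupper(sym)
      if (!(sym %in% names(DEFAULT_VALENCE)))
        fail(i, paste("unsupported element", sym))
      h <- if (nzchar(m[5])) {
        if (m[5] == "H") 1L else as.integer(substr(m[5], 2L, nchar(m[5])))
      } else 0L
      charge <- 0L
      if (nzchar(m[6])) {
        cs <- m[6]
        charge <- if (grepl("^[+-][0-9]+$", cs)) {
          as.integer(cs)
        } else {
          nchar(cs) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
        }
      }
      add_atom(sym, aromatic, charge, h)
      i <- j + 1L
    } else {
      two <- if (i < np) paste0(c1, ch[i + 1L]) else ""
      if (two %in% ORGANIC_TWO) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else if (c1 %in% ORGANIC_ONE) {
        add_atom(c1, FALSE)
        i <- i + 1L
      } else if (c1 %in% AROMATIC_ORGANIC) {
        add_atom(toupper(c1), TRUE)
        i <- i + 1L
      } else {
        fail(i, "unexpected character")
      }
    }
  }
  if (length(stack) > 0) stop_data("unclosed branch in SMILES")
  open_digits <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_digits) > 0)
    stop_data(paste("unclosed ring bond(s):",
                    paste(open_digits, collapse = ", ")))
  if (length(el) == 0) stop_data("SMILES contains no atoms")

  atoms <- data.frame(element = el, charge = chg, hcount = hc,
                      aromatic = arom, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b1, a2 = b2, order = bord,
                      stringsAsFactors = FALSE)
  mol <- structure(list(atoms = atoms, bonds = bonds, name = name,
                        coords = NULL), class = "hm_mol")
  mol <- perceive_rings(mol)
  if (any(atoms$aromatic & !mol$atoms$in_ring))
    stop_data("aromatic atom outside of a ring (cannot sanitize)")
  # hydrogen counts first (Kekule orders still explicit), then aromatize
  mol$atoms$hcount <- implicit_hydrogens(mol, explicit_h = hexp)
  mol <- aromatize(mol)
  new_molecule(mol$atoms, mol$bonds, name = name)
}
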