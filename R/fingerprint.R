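# Explicit-growth circular substructure fingerprint with full feature-to-
# bond provenance. For every heavy atom a substructure is grown outward one
# shell per iteration; each (center, iteration) substructure is serialized
# to a canonical, attachment-marked encoding and hashed into the feature id
# space. The fingerprint keeps, per feature id, every occurrence's exact
# atom and bond sets -- the bridge that lets model weights flow back onto
# the molecular graph.

#' Daylight-style atom invariants
#'
#' One row per heavy atom: atomic number, heavy-atom degree, attached
#' hydrogen count, formal charge, aromaticity flag, ring-membership flag.
#' The invariant is a function of the atom alone (given perception) and
#' seeds the canonical substructure encoding.
#'
#' @param mol an `hm_mol`.
#' @return integer matrix with 6 columns, index-aligned with atoms.
#' @export
atom_invariants <- function(mol) {
  cbind(atomic_number = PERIODIC[mol$atoms$element],
        degree = as.integer(mol$atoms$degree),
        hcount = as.integer(mol$atoms$hcount),
        charge = as.integer(mol$atoms$charge),
        aromatic = as.integer(mol$atoms$aromatic),
        in_ring = as.integer(mol$atoms$in_ring))
}

#' Grow circular substructures around every atom
#'
#' Iteration 0 is the center atom alone; iteration i+1 absorbs all
#' attachment-point atoms and exposes their not-yet-member neighbors as the
#' new attachment points. The bond set of a substructure contains every
#' bond among member atoms plus the bonds out to attachment points (those
#' carry weight in the coloring, so even an iteration-0 feature covers its
#' incident bonds). Growth for a center stops once its attachment set is
#' empty, i.e. the whole connected component is covered; no duplicate
#' substructures are emitted beyond that point.
#'
#' @param mol an `hm_mol`.
#' @param depth maximum iteration index (default 4).
#' @return a list of substructures, each a list with elements `center`,
#'   `iteration`, `member_atoms`, `member_bonds`, `attachment_points`.
#' @export
grow_substructures <- function(mol, depth = 4L) {
  stopifnot(depth >= 0)
  n <- n_atoms(mol)
  b1 <- mol$bonds$a1
  b2 <- mol$bonds$a2
  adj <- vector("list", n)
  for (i in seq_along(b1)) {
    adj[[b1[i]]] <- c(adj[[b1[i]]], b2[i])
    adj[[b2[i]]] <- c(adj[[b2[i]]], b1[i])
  }
  out <- vector("list", 0L)
  for (center in seq_len(n)) {
    # BFS distances from center
    dist <- rep(NA_integer_, n)
    dist[center] <- 0L
    frontier <- center
    d <- 0L
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      d <- d + 1L
      dist[nxt] <- d
      frontier <- nxt
    }
    for (it in 0L:depth) {
      inm <- !is.na(dist) & dist <= it
      att <- !is.na(dist) & dist == it + 1L
      bsel <- (inm[b1] & inm[b2]) | (inm[b1] & att[b2]) | (att[b1] & inm[b2])
      out[[length(out) + 1L]] <- list(
        center = center, iteration = it,
        member_atoms = which(inm),
        member_bonds = which(bsel),
        attachment_points = which(att))
      if (!any(att)) break
    }
  }
  out
}

#' Canonical encoding of a circular substructure
#'
#' Serializes the attachment-marked induced subgraph: member atoms carry
#' their atom-invariant tuple as node label, attachment points carry the
#' reserved wildcard `*` (an attachment matches any atom), and edges carry
#' the bond order. The serialization is a canonical graph certificate, so
#' isomorphic substructures produce identical text regardless of atom input
#' order.
#'
#' @param sub one element of [grow_substructures()].
#' @param mol the molecule the substructure belongs to.
#' @param invariants optional precomputed [atom_invariants()] matrix.
#' @return a character scalar.
#' @export
canonical_encoding <- function(sub, mol, invariants = atom_invariants(mol)) {
  labchr <- do.call(paste, c(lapply(seq_len(ncol(invariants)),
                                    function(j) invariants[, j]),
                             sep = "."))
  encode_substructure(sub, mol, labchr)
}

# hot path shared with fingerprint_molecule: atom labels precomputed
encode_substructure <- function(sub, mol, labchr) {
  nodes <- c(sub$member_atoms, sub$attachment_points)
  labels <- c(labchr[sub$member_atoms],
              rep("*", length(sub$attachment_points)))
  loc <- integer(length(labchr))
  loc[nodes] <- seq_along(nodes)
  eb <- sub$member_bonds
  edges <- cbind(loc[mol$bonds$a1[eb]], loc[mol$bonds$a2[eb]]) - 1L
  .canonical_certificate_cpp(labels,
                             matrix(as.integer(edges), ncol = 2),
                             as.character(mol$bonds$order[eb]))
}

#' Hash a canonical encoding into the feature id space
#'
#' Stable 64-bit FNV-1a hash masked to `hash_bits` bits; identical across
#' runs and platforms, never a per-process randomized hash, so persisted
#' models stay valid.
#'
#' @param encoding canonical encoding text.
#' @param hash_bits width of the feature id space in bits (default 22).
#' @return a non-negative numeric feature id `< 2^hash_bits`.
#' @export
hash_feature <- function(encoding, hash_bits = 22L) {
  stopifnot(hash_bits >= 1, hash_bits <= 32)
  vapply(encoding, function(e) .fnv1a_hash_cpp(e, as.integer(hash_bits)),
         numeric(1), USE.NAMES = FALSE)
}

#' Fingerprint a molecule with provenance
#'
#' Binary feature semantics: a feature occurring at several centers is
#' present once, but every occurrence (its member atom set and bond set) is
#' kept in the provenance. When two distinct canonical encodings hash to
#' the same feature id, the collision is visible in `encodings` and the
#' feature's occurrences include both substructures, so a model weight for
#' that id flows to all of them.
#'
#' @param mol an `hm_mol`.
#' @param depth maximum growth iteration (default 4).
#' @param hash_bits feature id space width (default 22).
#' @return an object of class `hm_fp` with fields `features` (sorted ids),
#'   `provenance` (id key -> list of occurrences with `atoms`, `bonds`),
#'   `encodings` (id key -> distinct canonical encodings), `mol`, `depth`,
#'   `hash_bits`.
#' @export
fingerprint_molecule <- function(mol, depth = 4L, hash_bits = 22L) {
  subs <- grow_substructures(mol, depth)
  inv <- atom_invariants(mol)
  labchr <- do.call(paste, c(lapply(seq_len(ncol(inv)),
                                    function(j) inv[, j]), sep = "."))
  bonds_chr <- as.character(mol$bonds$order)
  prov <- new.env(parent = emptyenv())
  encs <- new.env(parent = emptyenv())
  seen <- new.env(parent = emptyenv())
  ids <- numeric(0)
  for (sub in subs) {
    enc <- encode_substructure(sub, mol, labchr)
    id <- hash_feature(enc, hash_bits)
    key <- fid_key(id)
    occ_key <- paste(enc, paste(sub$member_atoms, collapse = ","),
                     paste(sub$member_bonds, collapse = ","))
    if (!is.null(seen[[occ_key]])) next  # identical occurrence, other center
    seen[[occ_key]] <- TRUE
    if (is.null(prov[[key]])) {
      prov[[key]] <- list()
      encs[[key]] <- character(0)
      ids <- c(ids, id)
    }
    prov[[key]][[length(prov[[key]]) + 1L]] <-
      list(atoms = sub$member_atoms, bonds = sub$member_bonds)
    if (!(enc %in% encs[[key]])) encs[[key]] <- c(encs[[key]], enc)
  }
  ids <- sort(ids)
  structure(list(features = ids,
                 provenance = as.list(prov),
                 encodings = as.list(encs),
                 mol = mol, depth = as.integer(depth),
                 hash_bits = as.integer(hash_bits)),
            class = "hm_fp")
}

#' @export
print.hm_fp <- function(x, ...) {
  ncoll <- sum(vapply(x$encodings, length, integer(1)) > 1)
  cat(sprintf("<fingerprint%s: %d features (depth %d, %d-bit), %d colliding>\n",
              if (nzchar(x$mol$name)) paste0(" of ", x$mol$name) else "",
              length(x$features), x$depth, x$hash_bits, ncoll))
  invisible(x)
}

#' Fingerprint many molecules
#'
#' @param mols list of `hm_mol`.
#' @inheritParams fingerprint_molecule
#' @return list of `hm_fp`.
#' @export
fingerprint_library <- function(mols, depth = 4L, hash_bits = 22L) {
  lapply(mols, fingerprint_molecule, depth = depth, hash_bits = hash_bits)
}

#' Collision statistics of a fingerprinted set
#'
#' Fraction of feature ids (union over the set) whose id maps to more than
#' one distinct canonical encoding.
#'
#' @param fps list of `hm_fp`.
#' @return list with `n_features`, `n_colliding`, `fraction`.
#' @export
collision_stats <- function(fps) {
  tab <- new.env(parent = emptyenv())
  for (fp in fps) {
    for (key in names(fp$encodings)) {
      tab[[key]] <- union(if (is.null(tab[[key]])) character(0) else tab[[key]],
                          fp$encodings[[key]])
    }
  }
  nn <- length(ls(tab))
  ncoll <- sum(vapply(ls(tab), function(k) length(tab[[k]]) > 1, logical(1)))
  list(n_features = nn, n_colliding = ncoll,
       fraction = if (nn > 0) ncoll / nn else 0)
}
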