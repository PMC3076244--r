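# Synthetic labeled molecule libraries with planted, weighted
# substructures. Molecules are assembled by attaching fragments at random
# open valences of randomly built alkyl/aryl scaffolds, which guarantees
# valid valences and realistic substructure sharing; actives receive the
# activating fragment(s) with a stated prevalence and the planted bond
# indices are recorded as ground truth, so the whole
# fingerprint -> model -> coloring chain can be scored against what was
# actually planted.

SCAFFOLD_PIECES <- c("CCCC", "CCC(C)C", "CCCCCC", "C1CCCCC1", "c1ccccc1",
                     "c1ccncc1", "CCOCC", "CC(C)CC")

DECOY_FRAGMENTS <- c("CCO", "CC=O", "CCN", "CC(C)C", "c1ccccc1", "CCSC")

#' Specification of a planted substructure
#'
#' @param smiles fragment SMILES; the attachment to the scaffold is made at
#'   a random open valence of the fragment.
#' @param effect `"activating"` or `"deactivating"`.
#' @param prevalence_active probability an active molecule carries the
#'   fragment.
#' @param prevalence_inactive probability an inactive molecule carries it.
#' @param name label used in the ground-truth annotation.
#' @return an `hm_plant`.
#' @export
plant_spec <- function(smiles, effect = c("activating", "deactivating"),
                       prevalence_active, prevalence_inactive,
                       name = effect) {
  effect <- match.arg(effect)
  stopifnot(prevalence_active >= 0, prevalence_active <= 1,
            prevalence_inactive >= 0, prevalence_inactive <= 1)
  parse_smiles(smiles)  # validate early
  structure(list(smiles = smiles, effect = effect,
                 prevalence_active = prevalence_active,
                 prevalence_inactive = prevalence_inactive, name = name),
            class = "hm_plant")
}

#' Default plant set: one activating, one deactivating fragment
#'
#' The activating furan-carboxamide is carried by every active and no
#' inactive (a clean, separable signal); the deactivating trichloromethyl
#' group is common in inactives (0.8) and rare in actives (0.1), so some
#' actives carry a genuinely negative-weighted substructure -- the
#' situation the coloring must resolve.
#'
#' @return list of two `hm_plant`.
#' @export
default_plants <- function() {
  list(plant_spec("NC(=O)c1ccco1", "activating", 1, 0, "activating"),
       plant_spec("ClC(Cl)Cl", "deactivating", 0.1, 0.8, "deactivating"))
}

# atoms with a spare hydrogen where a new single bond can be made
open_valence_atoms <- function(mol) which(mol$atoms$hcount >= 1L)

# attach `frag` to `mol` by a single bond; returns mol plus bookkeeping
join_molecules <- function(mol, frag, at_mol, at_frag) {
  off_a <- n_atoms(mol)
  off_b <- n_bonds(mol)
  atoms <- rbind(mol$atoms[, c("element", "charge", "hcount", "aromatic")],
                 frag$atoms[, c("element", "charge", "hcount", "aromatic")])
  bonds <- rbind(mol$bonds[, c("a1", "a2", "order")],
                 data.frame(a1 = frag$bonds$a1 + off_a,
                            a2 = frag$bonds$a2 + off_a,
                            order = frag$bonds$order))
  link <- data.frame(a1 = at_mol, a2 = at_frag + off_a, order = "single")
  bonds <- rbind(bonds, link)
  atoms$hcount[at_mol] <- atoms$hcount[at_mol] - 1L
  atoms$hcount[at_frag + off_a] <- atoms$hcount[at_frag + off_a] - 1L
  out <- new_molecule(atoms, bonds, name = mol$name)
  list(mol = out,
       frag_bonds = off_b + seq_len(n_bonds(frag)),
       link_bond = n_bonds(out))
}

build_scaffold <- function(pieces = SCAFFOLD_PIECES) {
  n_pieces <- sample(1:3, 1)
  mol <- parse_smiles(sample(pieces, 1))
  if (n_pieces > 1) {
    for (k in seq_len(n_pieces - 1)) {
      frag <- parse_smiles(sample(pieces, 1))
      a1 <- open_valence_atoms(mol)
      a2 <- open_valence_atoms(frag)
      if (length(a1) == 0 || length(a2) == 0) next
      mol <- join_molecules(mol, frag,
                            a1[sample.int(length(a1), 1)],
                            a2[sample.int(length(a2), 1)])$mol
    }
  }
  mol
}

#' Generate a labeled synthetic library with planted substructures
#'
#' Each molecule is a random scaffold plus 0-2 decoy fragments; plants are
#' attached according to their class prevalences and their internal bond
#' indices recorded as ground truth. Labels are flipped at the noise rate
#' (the ground-truth annotation keeps the pre-noise label). Fully
#' reproducible from `seed`; the caller's RNG state is untouched.
#'
#' @param n_active,n_inactive class sizes (>= 1).
#' @param plants list of `hm_plant` (default [default_plants()]).
#' @param scaffold_pool_size number of distinct random scaffolds to draw
#'   molecules from.
#' @param seed integer seed.
#' @param noise label flip probability (default 0).
#' @param decoys pool of uninformative fragment SMILES.
#' @param max_retries attempts to assemble a molecule before giving up.
#' @return an `hm_library`: `mols`, `labels` (post-noise), `true_labels`,
#'   `truth` (per molecule: plant name -> planted bond indices), `plants`.
#' @export
generate_library <- function(n_active, n_inactive,
                             plants = default_plants(),
                             scaffold_pool_size = 20L, seed = 1L,
                             noise = 0, decoys = DECOY_FRAGMENTS,
                             max_retries = 20L) {
  stopifnot(n_active >= 1, n_inactive >= 1, noise >= 0, noise <= 1)
  plant_mols <- lapply(plants, function(p) parse_smiles(p$smiles))
  decoy_mols <- lapply(decoys, parse_smiles)
  with_seed(seed, {
    pool <- replicate(scaffold_pool_size, build_scaffold(),
                      simplify = FALSE)
    n <- n_active + n_inactive
    true_labels <- c(rep(1L, n_active), rep(-1L, n_inactive))
    mols <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try_i in seq_len(max_retries)) {
        res <- tryCatch(
          assemble_molecule(pool, plant_mols, plants, decoy_mols,
                            true_labels[i]),
          error = function(e) NULL)
        if (!is.null(res)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_data("could not assemble a valid molecule")
      res$mol$name <- sprintf("mol%05d", i)
      mols[[i]] <- res$mol
      truth[[i]] <- res$truth
    }
    labels <- true_labels
    flip <- runif(n) < noise
    labels[flip] <- -labels[flip]
    names(mols) <- vapply(mols, function(m) m$name, character(1))
    names(truth) <- names(mols)
    structure(list(mols = mols, labels = labels, true_labels = true_labels,
                   truth = truth, plants = plants, seed = seed,
                   noise = noise),
              class = "hm_library")
  })
}

assemble_molecule <- function(pool, plant_mols, plants, decoy_mols,
                              label) {
  mol <- pool[[sample.int(length(pool), 1)]]
  truth <- list()
  n_decoy <- sample(0:2, 1)
  for (k in seq_len(n_decoy)) {
    frag <- decoy_mols[[sample.int(length(decoy_mols), 1)]]
    a1 <- open_valence_atoms(mol)
    a2 <- open_valence_atoms(frag)
    if (length(a1) == 0 || length(a2) == 0) next
    mol <- join_molecules(mol, frag, a1[sample.int(length(a1), 1)],
                          a2[sample.int(length(a2), 1)])$mol
  }
  for (j in seq_along(plants)) {
    p <- plants[[j]]
    prob <- if (label == 1L) p$prevalence_active else p$prevalence_inactive
    if (runif(1) >= prob) next
    frag <- plant_mols[[j]]
    a1 <- open_valence_atoms(mol)
    a2 <- open_valence_atoms(frag)
    if (length(a1) == 0 || length(a2) == 0)
      stop_data("no open valence for plant")
    jr <- join_molecules(mol, frag, a1[sample.int(length(a1), 1)],
                         a2[sample.int(length(a2), 1)])
    mol <- jr$mol
    truth[[p$name]] <- c(truth[[p$name]], jr$frag_bonds)
  }
  list(mol = mol, truth = truth)
}

#' @export
print.hm_library <- function(x, ...) {
  cat(sprintf("<synthetic library: %d molecules (%d active / %d inactive), %d plant(s), noise %.2f>\n",
              length(x$mols), sum(x$true_labels == 1L),
              sum(x$true_labels == -1L), length(x$plants), x$noise))
  invisible(x)
}

#' Class-ratio presets for library generation
#'
#' `muv_shape()` mirrors the maximum-unbiased-validation benchmark shape
#' (30 diverse actives against 15,000 decoys) for scaled performance
#' checks; `desk_shape()` is the small default used by the test suite.
#'
#' @return list with `n_active`, `n_inactive`, usable as
#'   `do.call(generate_library, c(muv_shape(), list(seed = 1)))`.
#' @export
muv_shape <- function() list(n_active = 30L, n_inactive = 15000L)

#' @rdname muv_shape
#' @export
desk_shape <- function() list(n_active = 50L, n_inactive = 50L)

#' Score how well colorings recover the planted substructures
#'
#' For each true active that carries planted bonds of the requested effect,
#' the molecule counts as recovered when the mean normalized score over the
#' planted bonds exceeds (activating) or falls below (deactivating) the
#' mean over all its other bonds. Returns the recovered fraction.
#'
#' @param library an `hm_library`.
#' @param colorings list of `hm_coloring` named by molecule name (or
#'   index-aligned with the library).
#' @param effect which plant effect to score.
#' @return fraction in \[0, 1\].
#' @export
recovery_score <- function(library, colorings,
                           effect = c("activating", "deactivating")) {
  effect <- match.arg(effect)
  if (is.null(names(colorings)))
    names(colorings) <- vapply(colorings, function(cl) cl$name,
                               character(1))
  plant_names <- vapply(library$plants, function(p) p$name, character(1))
  wanted <- plant_names[vapply(library$plants,
                               function(p) p$effect == effect, logical(1))]
  hits <- logical(0)
  for (nm in names(colorings)) {
    if (!(nm %in% names(library$truth))) next
    if (library$true_labels[[match(nm, names(library$mols))]] != 1L) next
    planted <- unlist(library$truth[[nm]][wanted], use.names = FALSE)
    if (length(planted) == 0) next
    cl <- colorings[[nm]]
    others <- setdiff(seq_along(cl$nu), planted)
    if (length(others) == 0) next
    diff_mean <- mean(cl$nu[planted]) - mean(cl$nu[others])
    hits <- c(hits, if (effect == "activating") diff_mean > 0
              else diff_mean < 0)
  }
  if (length(hits) == 0)
    stop_data("no colorings with planted bonds of that effect")
  mean(hits)
}

#' Write a library to disk (SDF + label CSV + ground-truth JSON)
#'
#' @param library an `hm_library`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sdf(library$mols, file.path(dir, "library.sdf"))
  write.csv(data.frame(name = names(library$mols),
                       label = library$labels),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = library$seed, noise = library$noise,
         plants = lapply(library$plants, unclass),
         true_labels = library$true_labels,
         truth = library$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
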