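# Fixtures are built in code; no stored binary data.

# linear carbon chain with n atoms (n - 1 single bonds)
chain_mol <- function(n, name = paste0("chain", n)) {
  parse_smiles(paste(rep("C", n), collapse = ""), name = name)
}

# hand-built fingerprint: provenance given as list(feature_id = list of
# occurrences list(atoms =, bonds =)); molecule is a carbon chain with
# enough bonds
fake_fp <- function(provenance, n_bonds_wanted = NULL, depth = 4L,
                    hash_bits = 22L, name = "fake") {
  ids <- as.numeric(names(provenance))
  if (is.null(n_bonds_wanted)) {
    n_bonds_wanted <- max(c(1, unlist(lapply(provenance, function(o)
      unlist(lapply(o, `[[`, "bonds"))))))
  }
  mol <- chain_mol(n_bonds_wanted + 1L, name = name)
  prov <- provenance
  names(prov) <- sprintf("%.0f", ids)
  structure(list(features = sort(ids), provenance = prov,
                 encodings = setNames(as.list(sprintf("enc%s", names(prov))),
                                      names(prov)),
                 mol = mol, depth = as.integer(depth),
                 hash_bits = as.integer(hash_bits)),
            class = "hm_fp")
}

# features-only fingerprint (training does not need provenance)
sparse_fp <- function(ids, depth = 4L, hash_bits = 22L, name = "x") {
  fake_fp(setNames(lapply(ids, function(i)
    list(list(atoms = 1L, bonds = integer(0)))), as.character(ids)),
    n_bonds_wanted = 1L, depth = depth, hash_bits = hash_bits, name = name)
}

# hand-built model with weights named by numeric feature id
fake_model <- function(weights, bias = 0, depth = 4L, hash_bits = 22L) {
  structure(list(weights = setNames(as.numeric(weights),
                                    sprintf("%.0f",
                                            as.numeric(names(weights)))),
                 bias = bias, C = 1, negative_class_weight = 1,
                 depth = as.integer(depth),
                 hash_bits = as.integer(hash_bits),
                 min_count = NULL, converged = TRUE),
            class = "hm_model")
}

# independent brute-force triple loop (feature x occurrence x bond)
oracle_bond_scores <- function(model, fp, size_normalize = FALSE) {
  s <- numeric(n_bonds(fp$mol))
  for (b in seq_len(n_bonds(fp$mol))) {
    for (key in names(fp$provenance)) {
      w <- model$weights[key]
      if (is.na(w) || w == 0) next
      for (occ in fp$provenance[[key]]) {
        if (b %in% occ$bonds) {
          s[b] <- s[b] +
            if (size_normalize) w / length(occ$bonds) else w
        }
      }
    }
  }
  unname(s)
}

oracle_atom_scores <- function(model, fp) {
  s <- numeric(n_atoms(fp$mol))
  for (a in seq_len(n_atoms(fp$mol))) {
    for (key in names(fp$provenance)) {
      w <- model$weights[key]
      if (is.na(w) || w == 0) next
      for (occ in fp$provenance[[key]])
        if (a %in% occ$atoms) s[a] <- s[a] + w
    }
  }
  unname(s)
}

# random-weight model covering every feature of a fingerprint set
random_model <- function(fps, seed = 1, depth = fps[[1]]$depth,
                         hash_bits = fps[[1]]$hash_bits) {
  ids <- sort(unique(unlist(lapply(fps, function(f) f$features))))
  set.seed(seed)
  w <- setNames(round(runif(length(ids), -2, 2), 3), ids)
  fake_model(w, bias = 0, depth = depth, hash_bits = hash_bits)
}

# permute the atom order (and shuffle bond rows) of a molecule;
# returns the permuted molecule plus index maps back to the original
permute_molecule <- function(mol, seed = 1) {
  set.seed(seed)
  n <- n_atoms(mol)
  perm <- sample.int(n)  # perm[old] = new
  atoms <- mol$atoms[order(perm), c("element", "charge", "hcount",
                                    "aromatic")]
  rownames(atoms) <- NULL
  bperm <- sample.int(n_bonds(mol))  # new row i is old bond bperm[i]
  bonds <- data.frame(a1 = perm[mol$bonds$a1[bperm]],
                      a2 = perm[mol$bonds$a2[bperm]],
                      order = mol$bonds$order[bperm])
  list(mol = new_molecule(atoms, bonds, name = mol$name),
       atom_map = perm, bond_map = bperm)
}

# small seeded set of diverse valid SMILES used across tests
test_smiles <- c(
  "CCO", "CCC", "c1ccccc1", "c1ccncc1", "CC(C)Cc1ccccc1",
  "NC(=O)c1ccco1", "ClC(Cl)Cl", "CCS(=O)(=O)N", "C1CCCCC1",
  "OCC(O)CO", "CC(=O)Oc1ccccc1", "c1ccc2ccccc2c1", "C1=CC=CS1",
  "CCN(CC)CC", "O=[N+]([O-])c1ccccc1"
)

run_py <- function(code) {
  out <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}
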