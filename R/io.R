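# Sparse fingerprint file exchange. One molecule per line:
#   <label-or-name> <feature_id>:1 <feature_id>:1 ...
# feature ids ascending; a header comment pins the fingerprint
# configuration so downstream consumers can refuse mismatched data. The
# provenance sidecar is a TSV: molecule, feature id, occurrence index,
# comma-separated (1-based) bond indices.

#' Write fingerprints as sparse label:value lines
#'
#' @param fps list of `hm_fp`.
#' @param path output path.
#' @param labels optional vector in \{-1, +1\}; when absent the molecule
#'   name is used as the first column.
#' @return `path`, invisibly.
#' @export
write_sparse_fingerprints <- function(fps, path, labels = NULL) {
  if (!is.null(labels) && length(labels) != length(fps))
    stop_data("fingerprint / label count mismatch")
  cfg <- fps[[1]]
  lines <- c(sprintf("# svmheatmap sparse fingerprints depth=%d hash_bits=%d",
                     cfg$depth, cfg$hash_bits))
  for (i in seq_along(fps)) {
    fp <- fps[[i]]
    first <- if (is.null(labels)) fp$mol$name else
      sprintf("%+d", as.integer(labels[i]))
    lines <- c(lines, paste(
      first,
      paste0(fid_key(sort(fp$features)), ":1", collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read sparse fingerprints written by [write_sparse_fingerprints()]
#'
#' The result carries features only (no provenance, no molecule); it is
#' sufficient for training and decision values, not for coloring.
#'
#' @param path input path.
#' @return list with `fps` (feature-only `hm_fp` objects), `labels`
#'   (integer or NULL), `depth`, `hash_bits`.
#' @export
read_sparse_fingerprints <- function(path) {
  if (!file.exists(path)) stop_usage(paste("cannot read file:", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^# svmheatmap sparse fingerprints", lines, value = TRUE)
  if (length(hdr) != 1)
    stop_data("missing fingerprint configuration header")
  depth <- as.integer(sub(".*depth=(\\d+).*", "\\1", hdr))
  hash_bits <- as.integer(sub(".*hash_bits=(\\d+).*", "\\1", hdr))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(body) == 0) stop_data("no fingerprint records")
  fps <- list()
  labels <- integer(0)
  has_labels <- TRUE
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    first <- parts[1]
    feats <- as.numeric(sub(":.*$", "", parts[-1]))
    if (any(is.na(feats))) stop_data(paste("bad sparse line:", ln))
    lab <- suppressWarnings(as.integer(first))
    if (is.na(lab) || !(lab %in% c(-1L, 1L))) has_labels <- FALSE
    labels <- c(labels, lab)
    fps[[length(fps) + 1L]] <- structure(
      list(features = sort(feats), provenance = list(), encodings = list(),
           mol = structure(list(
             atoms = data.frame(), bonds = data.frame(),
             name = if (is.na(lab)) first else sprintf("row%d",
                                                       length(fps) + 1L),
             coords = NULL), class = "hm_mol"),
           depth = depth, hash_bits = hash_bits),
      class = "hm_fp")
  }
  list(fps = fps, labels = if (has_labels) labels else NULL,
       depth = depth, hash_bits = hash_bits)
}

#' Write the provenance sidecar table
#'
#' @param fps list of `hm_fp`.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(fps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("molecule\tfeature\toccurrence\tbonds", con)
  for (fp in fps) {
    for (key in names(fp$provenance)) {
      occs <- fp$provenance[[key]]
      for (k in seq_along(occs)) {
        writeLines(paste(fp$mol$name, key, k,
                         paste(occs[[k]]$bonds, collapse = ","),
                         sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read molecules from SDF or a SMILES file
#'
#' A `.smi`/`.smiles` file holds one molecule per line: SMILES, optionally
#' followed by whitespace and a name.
#'
#' @param path input path.
#' @return list of `hm_mol`.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop_usage(paste("cannot read file:", path))
  if (grepl("\\.(smi|smiles|txt)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) == 0) stop_data("no molecules in SMILES file")
    mols <- list()
    skipped <- 0L
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      nm <- if (length(parts) > 1) parts[2] else parts[1]
      m <- tryCatch(parse_smiles(parts[1], name = nm),
                    error = function(e) e)
      if (inherits(m, "error")) {
        warning(sprintf("skipping SMILES '%s': %s", parts[1],
                        conditionMessage(m)), call. = FALSE)
        skipped <- skipped + 1L
      } else mols[[length(mols) + 1L]] <- m
    }
    if (length(mols) == 0) stop_data("no parsable molecules")
    names(mols) <- vapply(mols, function(m) m$name, character(1))
    attr(mols, "n_skipped") <- skipped
    mols
  } else {
    read_sdf(path)
  }
}
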