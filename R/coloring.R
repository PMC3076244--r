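# Weight-to-bond attribution and color mapping. The score of a bond is the
# sum, over every feature occurrence whose bond set contains it, of that
# feature's model weight; scores are normalized to [0,1] either against the
# whole training set (full-set) or within one compound (single-molecule)
# and mapped onto a red -> orange -> green gradient built from two linear
# sub-gradients that meet at the orange midpoint.

#' Per-bond scores of a molecule under a linear model
#'
#' Each feature occurrence in the fingerprint's provenance contributes the
#' feature's weight to every bond in its bond set (bonds to attachment
#' points included). With `size_normalize = TRUE` the contribution is the
#' weight divided by the occurrence's bond count, spreading a feature's
#' weight evenly over its bonds; the default is off, which favors scaffold-
#' sized fragments and gives smoother colorings.
#'
#' @param model an `hm_model`.
#' @param fp an `hm_fp` with matching fingerprint configuration.
#' @param size_normalize divide each contribution by the fragment's bond
#'   count (default FALSE).
#' @return an `hm_bondscores`: numeric `scores` (one per bond, 0 where no
#'   weighted feature covers the bond), the molecule, and flags.
#' @export
bond_scores <- function(model, fp, size_normalize = FALSE) {
  check_config(model, fp)
  s <- numeric(n_bonds(fp$mol))
  keys <- fid_key(fp$features)
  keys <- keys[keys %in% names(model$weights)]
  for (key in keys) {
    w <- model$weights[[key]]
    if (w == 0) next
    for (occ in fp$provenance[[key]]) {
      if (length(occ$bonds) == 0) next
      contrib <- if (size_normalize) w / length(occ$bonds) else w
      s[occ$bonds] <- s[occ$bonds] + contrib
    }
  }
  structure(list(scores = s, molecule = fp$mol, name = fp$mol$name,
                 size_normalized = size_normalize),
            class = "hm_bondscores")
}

#' Per-atom scores (analog of bond scores)
#'
#' Same attribution with member atom sets instead of bond sets. Provided
#' for completeness; the default renderer colors bonds and uses element
#' type colors for atoms.
#'
#' @inheritParams bond_scores
#' @return numeric vector, one score per atom.
#' @export
atom_scores <- function(model, fp, size_normalize = FALSE) {
  check_config(model, fp)
  s <- numeric(n_atoms(fp$mol))
  keys <- fid_key(fp$features)
  keys <- keys[keys %in% names(model$weights)]
  for (key in keys) {
    w <- model$weights[[key]]
    if (w == 0) next
    for (occ in fp$provenance[[key]]) {
      contrib <- if (size_normalize) w / length(occ$atoms) else w
      s[occ$atoms] <- s[occ$atoms] + contrib
    }
  }
  s
}

#' Normalization context for score-to-color mapping
#'
#' `single_molecule` takes the extremes of exactly one compound's score
#' map, maximizing within-molecule contrast; `full_set` takes the global
#' extremes over the training set plus the compounds of interest, keeping
#' cross-compound differences comparable (one shared affine map).
#'
#' @param mode `"single_molecule"` or `"full_set"`.
#' @param scoremaps list of `hm_bondscores` (exactly one for
#'   single-molecule mode).
#' @return an `hm_normctx` with `mode`, `s_min`, `s_max`.
#' @export
normalization_context <- function(mode = c("single_molecule", "full_set"),
                                  scoremaps) {
  mode <- match.arg(mode)
  if (inherits(scoremaps, "hm_bondscores")) scoremaps <- list(scoremaps)
  if (length(scoremaps) == 0) stop_data("no score maps given")
  if (mode == "single_molecule" && length(scoremaps) != 1)
    stop_data("single_molecule normalization takes exactly one score map")
  all_scores <- unlist(lapply(scoremaps, function(x) x$scores),
                       use.names = FALSE)
  if (length(all_scores) == 0) stop_data("score maps contain no bonds")
  structure(list(mode = mode, s_min = min(all_scores),
                 s_max = max(all_scores)),
            class = "hm_normctx")
}

#' Normalize a raw bond score to \[0, 1\]
#'
#' Affine map (score - s_min) / (s_max - s_min), clamped to \[0, 1\] for
#' scores outside the context (possible when an external compound is scored
#' under a full-set context). A degenerate context (s_max == s_min) maps
#' everything to the neutral midpoint 0.5 rather than asserting importance
#' that the scores cannot resolve.
#'
#' @param score numeric vector of raw scores.
#' @param ctx an `hm_normctx`.
#' @return numeric vector in \[0, 1\].
#' @export
normalize_score <- function(score, ctx) {
  stopifnot(inherits(ctx, "hm_normctx"))
  if (ctx$s_max == ctx$s_min) return(rep(0.5, length(score)))
  pmin(1, pmax(0, (score - ctx$s_min) / (ctx$s_max - ctx$s_min)))
}

#' Default red-orange-green gradient anchors
#'
#' @return a `Gradient`: list of RGB triples `negative` (red 255,0,0),
#'   `mid` (orange 255,165,0), `positive` (green 0,200,0).
#' @export
default_gradient <- function() {
  structure(list(negative = c(255L, 0L, 0L), mid = c(255L, 165L, 0L),
                 positive = c(0L, 200L, 0L)),
            class = "hm_gradient")
}

check_gradient <- function(g) {
  ok <- all(vapply(g[c("negative", "mid", "positive")], function(v)
    length(v) == 3 && all(v >= 0 & v <= 255), logical(1)))
  if (!ok) stop_data("gradient channels must be length-3 in 0..255")
  invisible(TRUE)
}

#' Map a normalized score to an RGB color
#'
#' Two linear sub-gradients: for nu <= 0.5 each channel mixes the negative
#' and mid anchors at t = 2 nu; for nu > 0.5 the mid and positive anchors
#' at t = 2 nu - 1. Both sides reach the mid color exactly at nu = 0.5, so
#' the combined map is continuous. Channels are rounded half-up to
#' integers.
#'
#' @param nu numeric vector of normalized scores in \[0, 1\].
#' @param gradient anchor colors, see [default_gradient()].
#' @return integer matrix with columns r, g, b (one row per score).
#' @export
score_to_color <- function(nu, gradient = default_gradient()) {
  check_gradient(gradient)
  if (any(is.na(nu)) || any(nu < 0 | nu > 1))
    stop_data("normalized scores must lie in [0, 1]; normalize first")
  lo <- nu <= 0.5
  out <- matrix(0L, nrow = length(nu), ncol = 3,
                dimnames = list(NULL, c("r", "g", "b")))
  for (chan in 1:3) {
    a <- gradient$negative[chan]; m <- gradient$mid[chan]
    p <- gradient$positive[chan]
    v <- numeric(length(nu))
    t1 <- 2 * nu[lo]
    v[lo] <- a + t1 * (m - a)
    t2 <- 2 * nu[!lo] - 1
    v[!lo] <- m + t2 * (p - m)
    out[, chan] <- as.integer(round_half_up(v))
  }
  out
}

#' Color every bond of a molecule from a trained model
#'
#' Composition of [bond_scores()], [normalize_score()] and
#' [score_to_color()]. Full-set mode requires score maps of the training
#' data set (plus any other compounds of interest); they define the shared
#' normalization context together with this compound's own map.
#'
#' @inheritParams bond_scores
#' @param mode normalization mode.
#' @param training_scoremaps list of `hm_bondscores` for full-set mode.
#' @param gradient anchor colors.
#' @return an `hm_coloring` with raw scores, normalized scores `nu`, an
#'   RGB matrix, hex colors, the molecule, the normalization mode and the
#'   compound's decision value.
#' @export
color_molecule <- function(model, fp,
                           mode = c("single_molecule", "full_set"),
                           training_scoremaps = NULL,
                           size_normalize = FALSE,
                           gradient = default_gradient()) {
  mode <- match.arg(mode)
  bsm <- bond_scores(model, fp, size_normalize)
  if (mode == "full_set") {
    if (is.null(training_scoremaps))
      stop_data(paste("full_set normalization requires the score maps of",
                      "the whole training data set (training_scoremaps)"))
    ctx <- normalization_context("full_set", c(training_scoremaps,
                                               list(bsm)))
  } else {
    ctx <- normalization_context("single_molecule", list(bsm))
  }
  nu <- normalize_score(bsm$scores, ctx)
  rgb <- score_to_color(nu, gradient)
  structure(list(molecule = fp$mol, name = fp$mol$name,
                 raw = bsm$scores, nu = nu, rgb = rgb, hex = rgb_hex(rgb),
                 mode = mode, context = ctx,
                 size_normalized = size_normalize,
                 decision = decision_value(model, fp)),
            class = "hm_coloring")
}

#' @export
print.hm_coloring <- function(x, ...) {
  cat(sprintf("<coloring%s: %d bonds, %s normalization, f(x) = %.3f>\n",
              if (nzchar(x$name)) paste0(" of ", x$name) else "",
              length(x$raw), x$mode, x$decision))
  invisible(x)
}

#' Export colorings as a CSV table
#'
#' One row per bond: molecule, bond index (1-based), the two atom indices,
#' raw score, normalized score and hex color.
#'
#' @param colorings list of `hm_coloring`.
#' @param path output path.
#' @return the data.frame, invisibly.
#' @export
write_coloring_csv <- function(colorings, path) {
  if (inherits(colorings, "hm_coloring")) colorings <- list(colorings)
  rows <- lapply(colorings, function(cl) {
    nb <- length(cl$raw)
    data.frame(molecule = rep(cl$name, nb), bond = seq_len(nb),
               a1 = cl$molecule$bonds$a1, a2 = cl$molecule$bonds$a2,
               score = cl$raw, nu = cl$nu, color = cl$hex)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
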