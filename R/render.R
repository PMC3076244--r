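# SVG depiction of heat-map-colored molecules. Pure view layer: scores are
# never altered here. Layout is a deterministic Kamada-Kawai embedding
# seeded from a circular arrangement (chemist-grade depiction conventions
# such as wedge bonds are out of scope); every bond becomes exactly one
# stroke whose color is its heat color, atoms get CPK-style element labels
# (carbon implicit).

CPK_PALETTE <- c(C = "#000000", N = "#3050F8", O = "#FF0D0D", S = "#C8A000",
                 P = "#FF8000", F = "#90E050", Cl = "#1FF01F",
                 Br = "#A62929", I = "#940094", B = "#FFB5B5",
                 H = "#808080")

#' Depiction style
#'
#' @param width,height canvas size in px.
#' @param bond_width stroke width in px.
#' @param background background color.
#' @param legend draw a gradient legend bar.
#' @param atom_palette named vector of label colors by element.
#' @param margin canvas margin in px.
#' @return an `hm_style` list.
#' @export
depiction_style <- function(width = 300, height = 300, bond_width = 5,
                            background = "#FFFFFF", legend = FALSE,
                            atom_palette = CPK_PALETTE, margin = 30) {
  stopifnot(width > 0, height > 0, bond_width > 0, margin >= 0)
  structure(list(width = width, height = height, bond_width = bond_width,
                 background = background, legend = legend,
                 atom_palette = atom_palette, margin = margin),
            class = "hm_style")
}

#' Deterministic 2D coordinates for a molecule
#'
#' Kamada-Kawai layout started from a circular arrangement (both
#' deterministic), scaled to unit median bond length. Used when a molecule
#' carries no depiction coordinates.
#'
#' @param mol an `hm_mol`.
#' @return an n x 2 coordinate matrix.
#' @export
layout2d <- function(mol) {
  n <- n_atoms(mol)
  if (n == 1) return(matrix(0, 1, 2))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n_bonds(mol) > 0)
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  start <- igraph::layout_in_circle(g)
  xy <- igraph::layout_with_kk(g, coords = start, maxiter = 500L)
  if (n_bonds(mol) > 0) {
    len <- sqrt((xy[mol$bonds$a1, 1] - xy[mol$bonds$a2, 1])^2 +
                  (xy[mol$bonds$a1, 2] - xy[mol$bonds$a2, 2])^2)
    med <- stats::median(len)
    if (is.finite(med) && med > 0) xy <- xy / med
  }
  round(xy, 6)
}

# scale molecule coordinates into the pixel box of a style
pixel_coords <- function(xy, style, box_w = style$width,
                         box_h = style$height) {
  mg <- style$margin
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  spanx <- max(rx[2] - rx[1], 1e-9)
  spany <- max(ry[2] - ry[1], 1e-9)
  sc <- min((box_w - 2 * mg) / spanx, (box_h - 2 * mg) / spany)
  px <- (xy[, 1] - mean(rx)) * sc + box_w / 2
  py <- (mean(ry) - xy[, 2]) * sc + box_h / 2  # SVG y grows downward
  cbind(px, py)
}

svg_num <- function(x) sprintf("%.2f", x)

# SVG fragment (no header) for one colored molecule, origin at (0,0)
svg_molecule_group <- function(coloring, style, box_w = style$width,
                               box_h = style$height, caption = NULL) {
  mol <- coloring$molecule
  xy <- if (!is.null(mol$coords)) mol$coords else layout2d(mol)
  p <- pixel_coords(xy, style, box_w, box_h)
  out <- character(0)
  nb <- n_bonds(mol)
  for (b in seq_len(nb)) {
    a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
    out <- c(out, sprintf(
      '<line class="bond" data-bond="%d" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-linecap="round"/>',
      b, svg_num(p[a1, 1]), svg_num(p[a1, 2]),
      svg_num(p[a2, 1]), svg_num(p[a2, 2]),
      coloring$hex[b], svg_num(style$bond_width)))
  }
  show <- which(mol$atoms$element != "C" | mol$atoms$charge != 0 |
                  nb == 0)
  for (a in show) {
    el <- mol$atoms$element[a]
    col <- style$atom_palette[[el]] %||% "#000000"
    lab <- el
    if (mol$atoms$charge[a] > 0)
      lab <- paste0(lab, strrep("+", mol$atoms$charge[a]))
    if (mol$atoms$charge[a] < 0)
      lab <- paste0(lab, strrep("-", -mol$atoms$charge[a]))
    out <- c(out, sprintf(
      '<circle class="atom-bg" cx="%s" cy="%s" r="8" fill="%s"/>',
      svg_num(p[a, 1]), svg_num(p[a, 2]), style$background),
      sprintf(
        '<text class="atom" data-atom="%d" x="%s" y="%s" fill="%s" font-size="11" font-family="sans-serif" text-anchor="middle" dominant-baseline="central">%s</text>',
        a, svg_num(p[a, 1]), svg_num(p[a, 2]), col, lab))
  }
  if (!is.null(caption)) {
    out <- c(out, sprintf(
      '<text class="caption" x="%s" y="%s" fill="#000000" font-size="11" font-family="sans-serif" text-anchor="middle">%s</text>',
      svg_num(box_w / 2), svg_num(box_h - 6), caption))
  }
  out
}

svg_legend <- function(style, gradient = default_gradient(),
                       n_steps = 100L) {
  w <- style$width - 2 * style$margin
  x0 <- style$margin
  y0 <- style$height - 12
  step <- w / n_steps
  nu <- (seq_len(n_steps) - 0.5) / n_steps
  cols <- rgb_hex(score_to_color(nu, gradient))
  c('<g class="legend">',
    sprintf('<rect x="%s" y="%s" width="%s" height="8" fill="%s"/>',
            svg_num(x0 + (seq_len(n_steps) - 1) * step), svg_num(y0),
            svg_num(step + 0.5), cols),
    "</g>")
}

svg_header <- function(w, h, background) {
  c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    round(w), round(h), round(w), round(h)),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="%s"/>',
            round(w), round(h), background))
}

#' Render a colored molecule to SVG
#'
#' Each bond is drawn exactly once as a line stroke in its heat color;
#' non-carbon atoms get element-colored labels. Output is deterministic:
#' identical input produces byte-identical SVG.
#'
#' @param coloring an `hm_coloring`.
#' @param style an `hm_style`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_svg <- function(coloring, style = depiction_style(), path) {
  stopifnot(inherits(coloring, "hm_coloring"), inherits(style, "hm_style"))
  lines <- c(svg_header(style$width, style$height, style$background),
             svg_molecule_group(coloring, style),
             if (style$legend) svg_legend(style),
             "</svg>")
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) stop_usage(paste("cannot write SVG:",
                                          conditionMessage(e))))
  invisible(path)
}

#' Render a grid of colored molecules to one SVG
#'
#' Panels are laid out row-major; each panel is captioned with the molecule
#' name and its prediction value to 3 decimals (single-molecule colorings
#' carry no absolute scale, so the prediction value compensates).
#'
#' @param colorings non-empty list of `hm_coloring`.
#' @param style an `hm_style` (per panel size).
#' @param path output file path.
#' @param ncol panels per row.
#' @return `path`, invisibly.
#' @export
render_grid <- function(colorings, style = depiction_style(), path,
                        ncol = NULL) {
  if (inherits(colorings, "hm_coloring")) colorings <- list(colorings)
  if (length(colorings) == 0) stop_data("no colorings to render")
  n <- length(colorings)
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  W <- style$width * ncol
  H <- style$height * nrow
  lines <- svg_header(W, H, style$background)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol
    cpos <- (i - 1) %% ncol
    cl <- colorings[[i]]
    cap <- sprintf("%s  f(x) = %.3f", cl$name, cl$decision)
    lines <- c(lines,
               sprintf('<g class="panel" transform="translate(%d,%d)">',
                       cpos * style$width, r * style$height),
               svg_molecule_group(cl, style, caption = cap),
               "</g>")
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
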