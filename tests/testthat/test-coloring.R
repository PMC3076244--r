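test_that("bond scores match the hand-computed attribution", {
  # feature f (w = 2.0) covers bonds {1,2}; g (w = -0.5) covers {2}
  fp <- fake_fp(list("101" = list(list(atoms = 1:3, bonds = c(1L, 2L))),
                     "202" = list(list(atoms = 2:3, bonds = 2L))))
  m <- fake_model(c("101" = 2.0, "202" = -0.5))
  expect_equal(bond_scores(m, fp)$scores, c(2.0, 1.5))
  # size-normalized: w/|B| per bond
  expect_equal(bond_scores(m, fp, size_normalize = TRUE)$scores,
               c(1.0, 0.5))
  # all-zero weights give all-zero scores
  z <- fake_model(c("101" = 0, "202" = 0))
  expect_equal(bond_scores(z, fp)$scores, c(0, 0))
  # every bond has an entry even when uncovered
  fp2 <- fake_fp(list("101" = list(list(atoms = 1:2, bonds = 1L))),
                 n_bonds_wanted = 3)
  expect_equal(bond_scores(m, fp2)$scores, c(2, 0, 0))
  expect_error(bond_scores(m, fake_fp(list("101" = list(
    list(atoms = 1L, bonds = 1L))), depth = 2)), "incompatible")
})

test_that("multiple occurrences each contribute the feature's weight", {
  fp <- fake_fp(list("77" = list(list(atoms = 1:2, bonds = 1L),
                                 list(atoms = 3:4, bonds = 3L))),
                n_bonds_wanted = 3)
  m <- fake_model(c("77" = 1.25))
  expect_equal(bond_scores(m, fp)$scores, c(1.25, 0, 1.25))
})

test_that("bond and atom scores equal the brute-force oracle", {
  set.seed(31)
  lib <- generate_library(10, 10, seed = 5)
  fps <- fingerprint_library(lib$mols, depth = 3)
  model <- random_model(fps, seed = 2)
  for (fp in fps) {
    expect_equal(bond_scores(model, fp)$scores,
                 oracle_bond_scores(model, fp))
    expect_equal(bond_scores(model, fp, TRUE)$scores,
                 oracle_bond_scores(model, fp, TRUE))
    expect_equal(atom_scores(model, fp), oracle_atom_scores(model, fp))
  }
})

test_that("bond scores are additive in the model weights", {
  lib <- generate_library(5, 5, seed = 9)
  fps <- fingerprint_library(lib$mols, depth = 3)
  m1 <- random_model(fps, seed = 11)
  m2 <- random_model(fps, seed = 12)
  m3 <- fake_model(setNames(m1$weights + m2$weights[names(m1$weights)],
                            names(m1$weights)), depth = 3)
  for (fp in fps) {
    expect_equal(bond_scores(m3, fp)$scores,
                 bond_scores(m1, fp)$scores + bond_scores(m2, fp)$scores)
  }
})

test_that("normalization contexts take the right extremes", {
  sm <- function(v) structure(list(scores = v, molecule = NULL,
                                   name = "x", size_normalized = FALSE),
                              class = "hm_bondscores")
  ctx <- normalization_context("single_molecule", sm(c(-1, 0, 3)))
  expect_equal(c(ctx$s_min, ctx$s_max), c(-1, 3))
  ctx2 <- normalization_context("full_set", list(sm(c(-1, 0)), sm(c(2, 5))))
  expect_equal(c(ctx2$s_min, ctx2$s_max), c(-1, 5))
  expect_error(normalization_context("single_molecule",
                                     list(sm(1), sm(2))), "exactly one")
  expect_error(normalization_context("full_set", list()), "no score maps")
})

test_that("normalize maps endpoints, midpoint, degenerate and clamps", {
  ctx <- structure(list(mode = "single_molecule", s_min = -2, s_max = 2),
                   class = "hm_normctx")
  expect_equal(normalize_score(c(-2, 0, 2), ctx), c(0, 0.5, 1))
  expect_equal(normalize_score(c(-5, 7), ctx), c(0, 1))  # clamped
  dg <- structure(list(mode = "single_molecule", s_min = 7, s_max = 7),
                  class = "hm_normctx")
  expect_equal(normalize_score(7, dg), 0.5)
})

test_that("both normalization modes preserve within-molecule ranking", {
  set.seed(41)
  for (rep_i in 1:25) {
    v1 <- rnorm(8)
    v2 <- rnorm(8) + 2
    sm <- function(v) structure(list(scores = v), class = "hm_bondscores")
    cs <- normalization_context("single_molecule", sm(v1))
    cf <- normalization_context("full_set", list(sm(v1), sm(v2)))
    n1 <- normalize_score(v1, cs)
    n2 <- normalize_score(v1, cf)
    expect_equal(order(n1), order(v1))
    expect_equal(order(n2), order(v1))
    # shared affine map: cross-molecule differences preserved up to scale
    nf <- normalize_score(c(v1, v2), cf)
    d <- diff(range(c(v1, v2)))
    expect_equal(nf, (c(v1, v2) - min(c(v1, v2))) / d)
  }
})

test_that("the two-part gradient hits its anchors and stays continuous", {
  g <- default_gradient()
  expect_equal(unname(score_to_color(0, g)[1, ]), c(255L, 0L, 0L))
  expect_equal(unname(score_to_color(0.5, g)[1, ]), c(255L, 165L, 0L))
  expect_equal(unname(score_to_color(1, g)[1, ]), c(0L, 200L, 0L))
  eps <- 1e-9
  expect_equal(score_to_color(0.5 - eps, g), score_to_color(0.5 + eps, g))
  expect_error(score_to_color(-0.01), "normalize")
  expect_error(score_to_color(1.01), "normalize")
  # custom anchors are honored
  g2 <- structure(list(negative = c(0L, 0L, 255L), mid = c(255L, 255L, 255L),
                       positive = c(255L, 0L, 0L)), class = "hm_gradient")
  expect_equal(unname(score_to_color(0, g2)[1, ]), c(0L, 0L, 255L))
})

test_that("zero-weight features never change a coloring", {
  lib <- generate_library(5, 5, seed = 13)
  fps <- fingerprint_library(lib$mols, depth = 3)
  m <- random_model(fps, seed = 3)
  m0 <- m
  extra <- setNames(rep(0, 5), sprintf("%.0f", 4e6 + 1:5))
  m0$weights <- c(m0$weights, extra)
  for (fp in fps[1:4])
    expect_identical(color_molecule(m, fp)$hex, color_molecule(m0, fp)$hex)
})

test_that("color_molecule composes scores, normalization and gradient", {
  fp <- fake_fp(list("101" = list(list(atoms = 1:3, bonds = c(1L, 2L))),
                     "202" = list(list(atoms = 2:3, bonds = 2L))),
                n_bonds_wanted = 3)
  m <- fake_model(c("101" = 2.0, "202" = -0.5), bias = 0.25)
  cl <- color_molecule(m, fp)
  expect_equal(cl$raw, c(2.0, 1.5, 0))
  expect_equal(cl$nu, c(1, 0.75, 0))
  expect_equal(cl$hex[1], "#00C800")  # green anchor at nu = 1
  expect_equal(cl$hex[3], "#FF0000")  # red anchor at nu = 0
  expect_equal(cl$decision, 0.25 + 2.0 - 0.5)

  # degenerate: all-zero model gives a uniform mid color
  z <- fake_model(c("101" = 0))
  clz <- color_molecule(z, fp)
  expect_true(all(clz$nu == 0.5))
  expect_true(all(clz$hex == "#FFA500"))

  # full_set requires the training maps, then shares one affine map
  expect_error(color_molecule(m, fp, mode = "full_set"), "training")
  other <- bond_scores(m, fake_fp(list("101" = list(
    list(atoms = 1:2, bonds = 1L))), n_bonds_wanted = 2))
  clf <- color_molecule(m, fp, mode = "full_set",
                        training_scoremaps = list(other))
  expect_equal(order(clf$nu), order(cl$nu))  # rank preserved across modes
})

test_that("coloring CSV export has one row per bond", {
  fp <- fake_fp(list("101" = list(list(atoms = 1:3, bonds = c(1L, 2L)))),
                n_bonds_wanted = 4)
  m <- fake_model(c("101" = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_coloring_csv(color_molecule(m, fp), path)
  expect_equal(nrow(df), 4L)
  back <- read.csv(path)
  expect_equal(back$bond, 1:4)
  expect_match(back$color, "^#[0-9A-F]{6}$")
})
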