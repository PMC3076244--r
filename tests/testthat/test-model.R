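test_that("rare-feature filter honors the 'at least min_count' boundary", {
  # feature 10 in 2 molecules, 20 in exactly 3, 30 in 4 of 6
  fps <- list(sparse_fp(c(10, 20, 30)), sparse_fp(c(10, 20, 30)),
              sparse_fp(c(20, 30)), sparse_fp(c(30, 99)),
              sparse_fp(99), sparse_fp(99))
  data <- make_dataset(fps, c(1, 1, 1, -1, -1, -1))
  f3 <- filter_rare_features(data, 3)
  present <- sort(unique(unlist(lapply(f3$fps, `[[`, "features"))))
  expect_equal(present, c(20, 30, 99))       # 2 occurrences removed
  expect_true("10" %in% attr(f3, "filtered_features"))
  # provenance is retained for filtered features
  expect_true("10" %in% names(f3$fps[[1]]$provenance))
  # min_count 1 is the identity
  expect_identical(filter_rare_features(data, 1)$fps, data$fps)
  expect_error(filter_rare_features(make_dataset(
    list(sparse_fp(1), sparse_fp(2)), c(1, -1)), 2), "every feature")
})

test_that("training separates a planted feature and flips with labels", {
  set.seed(3)
  # actives all contain feature 500, inactives never
  fps <- c(lapply(1:20, function(i)
    sparse_fp(c(500, sample(1:50, 5)), name = paste0("a", i))),
    lapply(1:20, function(i)
      sparse_fp(sample(1:50, 6), name = paste0("i", i))))
  labels <- rep(c(1L, -1L), each = 20)
  data <- make_dataset(fps, labels)
  m <- train_linear_svm(data, C = 1, seed = 9)
  expect_gt(m$weights[["500"]], 0)
  sc <- vapply(fps, function(f) decision_value(m, f), numeric(1))
  expect_equal(mean(ifelse(sc >= 0, 1L, -1L) == labels), 1.0)

  mf <- train_linear_svm(make_dataset(fps, -labels), C = 1, seed = 9)
  expect_lt(mf$weights[["500"]], 0)
  expect_lt(max(abs(m$weights + mf$weights[names(m$weights)])), 1e-3)

  expect_error(train_linear_svm(make_dataset(fps[1:20], labels[1:20])),
               "both classes")

  # indistinguishable fingerprints with mixed labels: predictions sit
  # near the hyperplane (classification is "less certain")
  same <- lapply(1:10, function(i) sparse_fp(c(1, 2, 3)))
  msame <- suppressWarnings(train_linear_svm(
    make_dataset(same, rep(c(1L, -1L), 5)), C = 1, seed = 1))
  expect_lt(abs(decision_value(msame, same[[1]])), 0.1)
})

test_that("decision values equal bias plus present-feature weight sum", {
  m <- fake_model(c("7" = 1.5, "9" = -0.25), bias = 0.1)
  expect_equal(decision_value(m, sparse_fp(numeric(0))), 0.1)
  expect_equal(decision_value(m, sparse_fp(7)), 1.6)
  expect_equal(decision_value(m, sparse_fp(c(7, 9, 1234))), 1.35)
  # config mismatch is refused
  expect_error(decision_value(m, sparse_fp(7, depth = 2)), "incompatible")
  expect_error(decision_value(m, sparse_fp(7, hash_bits = 10)),
               "incompatible")
})

test_that("decision values match the solver's own reported values", {
  set.seed(11)
  fps <- lapply(1:40, function(i) sparse_fp(sample(1:80, 8)))
  labels <- rep(c(1L, -1L), 20)
  data <- make_dataset(fps, labels)
  m <- suppressWarnings(train_linear_svm(data, C = 2, seed = 4))
  mine <- vapply(data$fps, function(f) decision_value(m, f), numeric(1))
  expect_lt(max(abs(mine - m$fit_decision_values)), 1e-9)
})

test_that("training is invariant to dataset order", {
  set.seed(5)
  fps <- c(lapply(1:15, function(i) sparse_fp(c(3, sample(10:40, 4)))),
           lapply(1:15, function(i) sparse_fp(sample(10:40, 5))))
  labels <- rep(c(1L, -1L), each = 15)
  m1 <- train_linear_svm(make_dataset(fps, labels), seed = 2)
  perm <- sample(seq_along(fps))
  m2 <- train_linear_svm(make_dataset(fps[perm], labels[perm]), seed = 2)
  sc1 <- vapply(fps, function(f) decision_value(m1, f), numeric(1))
  sc2 <- vapply(fps, function(f) decision_value(m2, f), numeric(1))
  expect_lt(abs(auc_score(sc1, labels) - auc_score(sc2, labels)), 1e-6)
})

test_that("hyperparameter search honors the grids and tie-breaks", {
  set.seed(8)
  fps <- c(lapply(1:12, function(i) sparse_fp(c(5, sample(20:60, 4)))),
           lapply(1:12, function(i) sparse_fp(sample(20:60, 5))))
  data <- make_dataset(fps, rep(c(1L, -1L), each = 12))
  one <- select_hyperparameters(data, C_grid = 4, W_grid = 0.5, seed = 1)
  expect_equal(one$C, 4)
  expect_equal(one$negative_class_weight, 0.5)
  # separable: every C reaches AUC 1, tie-break picks the smallest point
  sel <- select_hyperparameters(data, C_grid = 2^(-2:2), W_grid = c(0.5, 1),
                                seed = 1)
  expect_equal(sel$auc, 1.0)
  expect_equal(sel$C, 2^-2)
  expect_equal(sel$negative_class_weight, 0.5)
  expect_equal(nrow(sel$grid), 10L)
  # determinism
  sel2 <- select_hyperparameters(data, C_grid = 2^(-2:2),
                                 W_grid = c(0.5, 1), seed = 1)
  expect_identical(sel, sel2)
})

test_that("nested cross-validation reports folds and stays leak-free", {
  set.seed(21)
  fps <- c(lapply(1:20, function(i)
    sparse_fp(c(700, sample(1:60, 5)), name = paste0("a", i))),
    lapply(1:20, function(i)
      sparse_fp(sample(1:60, 6), name = paste0("i", i))))
  labels <- rep(c(1L, -1L), each = 20)
  data <- make_dataset(fps, labels)
  small_C <- 2^c(-2, 0, 2)
  ev <- evaluate_cv(data, folds = 5, repeats = 2, seed = 3,
                    C_grid = small_C, W_grid = 1)
  expect_equal(nrow(ev$folds), 10L)
  expect_true(all(ev$folds$auc >= 0 & ev$folds$auc <= 1))
  expect_true(all(ev$folds$acc >= 0 & ev$folds$acc <= 1))
  expect_gt(ev$mean_auc, 0.95)  # separable construction

  # poison probe: a feature present only in outer fold 1's held-out set
  # must never reach fold 1's model (filter + selection fit on train only)
  assign1 <- ev$assignments[[1]]
  poison <- 4e6
  pdata <- data
  pdata$fps <- lapply(seq_along(pdata$fps), function(i) {
    f <- pdata$fps[[i]]
    if (assign1[i] == 1L) f$features <- sort(c(f$features, poison))
    f
  })
  pev <- evaluate_cv(make_dataset(pdata$fps, labels), folds = 5,
                     repeats = 1, seed = 3, C_grid = small_C, W_grid = 1,
                     keep_models = TRUE)
  expect_identical(pev$assignments[[1]], assign1)
  expect_false(sprintf("%.0f", poison) %in% names(pev$models[[1]]$weights))
  # other folds train on the poisoned molecules, so they may see it
  expect_true(sprintf("%.0f", poison) %in% names(pev$models[[2]]$weights))
})

test_that("null labels give chance-level AUC", {
  set.seed(14)
  fps <- lapply(1:60, function(i) sparse_fp(sample(1:90, 6)))
  labels <- rep(c(1L, -1L), 30)
  ev <- evaluate_cv(make_dataset(fps, labels), folds = 5, repeats = 1,
                    seed = 2, C_grid = 1, W_grid = 1, min_count = 1)
  expect_lt(abs(ev$mean_auc - 0.5), 0.2)
})

test_that("models round-trip through JSON and refuse mismatched configs", {
  set.seed(6)
  fps <- c(lapply(1:10, function(i) sparse_fp(c(11, sample(30:60, 3)))),
           lapply(1:10, function(i) sparse_fp(sample(30:60, 4))))
  data <- make_dataset(fps, rep(c(1L, -1L), each = 10))
  m <- train_linear_svm(data, C = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  for (f in fps)
    expect_equal(decision_value(m2, f), decision_value(m, f))
  expect_error(decision_value(m2, sparse_fp(11, hash_bits = 16)),
               "incompatible")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(load_model(bad), "parse")
  writeLines('{"format": "other"}', bad)
  expect_error(load_model(bad), "model file")
})

test_that("the solver agrees with scikit-learn's liblinear on a fixture", {
  set.seed(17)
  nfeat <- 30
  rows <- lapply(1:40, function(i) sort(sample(0:(nfeat - 1), 6)))
  labels <- rep(c(1L, -1L), 20)
  fps <- lapply(rows, function(r) sparse_fp(r + 1))
  m <- suppressWarnings(train_linear_svm(make_dataset(fps, labels), C = 1,
                                         seed = 2, eps = 1e-8,
                                         max_iter = 20000))
  w_mine <- unname(m$weights[sprintf("%.0f", 1:nfeat)])
  w_mine[is.na(w_mine)] <- 0
  csv <- paste(vapply(seq_along(rows), function(i)
    paste(c(labels[i], rows[[i]]), collapse = ","), character(1)),
    collapse = ";")
  out <- run_py(paste0(
    "import numpy as np\n",
    "from sklearn.svm import LinearSVC\n",
    "rows='", csv, "'.split(';')\n",
    "X=np.zeros((len(rows),", nfeat, ")); y=[]\n",
    "for i,r in enumerate(rows):\n",
    "    p=[int(v) for v in r.split(',')]; y.append(p[0])\n",
    "    X[i,p[1:]]=1\n",
    "clf=LinearSVC(loss='hinge',C=1.0,tol=1e-10,max_iter=200000,",
    "intercept_scaling=1,random_state=0)\n",
    "clf.fit(X,y)\n",
    "print(','.join('%.6f'%v for v in clf.coef_[0]))\n",
    "print('%.6f'%clf.intercept_[0])\n"))
  w_sk <- as.numeric(strsplit(out[length(out) - 1], ",")[[1]])
  b_sk <- as.numeric(out[length(out)])
  expect_gt(stats::cor(w_mine, w_sk), 0.999)
  expect_lt(max(abs(w_mine - w_sk)), 0.05)
  expect_lt(abs(m$bias - b_sk), 0.05)
})
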