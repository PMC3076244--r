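# Linear max-margin classifier on provenance fingerprints. The solver is
# the classical dual coordinate descent for L2-regularized L1-loss linear
# SVC (the liblinear algorithm) with a per-class cost: the negative class
# cost is C * negative_class_weight. The bias is handled as an augmented
# constant feature.

#' Bundle fingerprints and labels into a labeled dataset
#'
#' @param fps list of `hm_fp` (all with the same depth/hash_bits).
#' @param labels vector in \{-1, +1\}, index-aligned with `fps`.
#' @return an object of class `hm_dataset`.
#' @export
make_dataset <- function(fps, labels) {
  labels <- as.integer(labels)
  if (length(fps) != length(labels))
    stop_data("fingerprint / label count mismatch")
  if (!all(labels %in% c(-1L, 1L)))
    stop_data("labels must be -1 or +1")
  cfg <- unique(t(vapply(fps, function(f) c(f$depth, f$hash_bits),
                         integer(2))))
  if (nrow(cfg) != 1) stop_data("mixed fingerprint configurations")
  structure(list(fps = fps, labels = labels,
                 depth = cfg[1, 1], hash_bits = cfg[1, 2]),
            class = "hm_dataset")
}

#' @export
print.hm_dataset <- function(x, ...) {
  cat(sprintf("<dataset: %d molecules (%d active / %d inactive), depth %d, %d-bit>\n",
              length(x$fps), sum(x$labels == 1L), sum(x$labels == -1L),
              x$depth, x$hash_bits))
  invisible(x)
}

dataset_subset <- function(data, idx) {
  structure(list(fps = data$fps[idx], labels = data$labels[idx],
                 depth = data$depth, hash_bits = data$hash_bits),
            class = "hm_dataset")
}

feature_counts <- function(data) {
  ids <- unlist(lapply(data$fps, function(f) f$features), use.names = FALSE)
  tab <- table(fid_key(ids))
  setNames(as.integer(tab), names(tab))
}

#' Remove features that occur in too few molecules
#'
#' A feature must be present in at least `min_count` molecules of the
#' (training) set to be kept; the default of 3 matches the usual
#' rare-feature cutoff for sparse screening fingerprints. Provenance and
#' encodings of removed features are retained on each fingerprint (a
#' coloring never consults features absent from the model anyway); the
#' removed ids are recorded in attribute `filtered_features`.
#'
#' @param data an `hm_dataset`.
#' @param min_count minimum number of molecules a feature must occur in.
#' @return a filtered `hm_dataset`.
#' @export
filter_rare_features <- function(data, min_count = 3L) {
  stopifnot(min_count >= 1)
  if (min_count == 1L) return(data)
  cnt <- feature_counts(data)
  keep <- names(cnt)[cnt >= min_count]
  if (length(keep) == 0)
    stop_data("rare-feature filter removed every feature")
  data$fps <- lapply(data$fps, function(f) {
    f$features <- f$features[fid_key(f$features) %in% keep]
    f
  })
  attr(data, "filtered_features") <- setdiff(names(cnt), keep)
  attr(data, "min_count") <- as.integer(min_count)
  data
}

# build 0-based row index lists against a fixed feature universe
design_rows <- function(fps, universe_keys) {
  lapply(fps, function(f) {
    cols <- match(fid_key(f$features), universe_keys)
    as.integer(sort(cols[!is.na(cols)])) - 1L
  })
}

#' Train a linear SVM on a labeled dataset
#'
#' L2-regularized hinge-loss linear classification (dual coordinate
#' descent) with the negative class's misclassification cost scaled by
#' `negative_class_weight`. Non-convergence within `max_iter` epochs emits
#' a warning carrying the solver diagnostics and is recorded in the model.
#'
#' @param data an `hm_dataset` containing both classes.
#' @param C soft-margin cost (> 0).
#' @param negative_class_weight multiplier on C for negative examples.
#' @param bias include a bias term (default TRUE).
#' @param eps dual violation tolerance for the stopping rule.
#' @param max_iter maximum coordinate descent epochs.
#' @param seed seed for the solver's coordinate permutation.
#' @return an object of class `hm_model` with per-feature `weights` (named
#'   by feature id; absent features have weight exactly 0), `bias`,
#'   hyperparameters and fingerprint configuration.
#' @export
train_linear_svm <- function(data, C = 1, negative_class_weight = 1,
                             bias = TRUE, eps = 1e-4, max_iter = 2000L,
                             seed = 1L) {
  stopifnot(inherits(data, "hm_dataset"), C > 0, negative_class_weight > 0)
  if (length(unique(data$labels)) < 2)
    stop_data("training requires both classes")
  universe <- sort(unique(unlist(lapply(data$fps, function(f) f$features),
                                 use.names = FALSE)))
  keys <- fid_key(universe)
  rows <- design_rows(data$fps, keys)
  fit <- .dcd_svm_cpp(rows, data$labels, length(universe),
                      Cpos = C, Cneg = C * negative_class_weight,
                      bias_term = bias, eps = eps,
                      max_iter = as.integer(max_iter), seed = as.integer(seed))
  if (!fit$converged)
    warning(sprintf(
      "solver did not converge: %d epochs, max dual violation %.3g (eps %.3g)",
      fit$iterations, fit$max_violation, eps), call. = FALSE)
  structure(list(weights = setNames(as.numeric(fit$weights), keys),
                 bias = fit$bias,
                 C = C, negative_class_weight = negative_class_weight,
                 depth = data$depth, hash_bits = data$hash_bits,
                 min_count = attr(data, "min_count", exact = TRUE),
                 converged = fit$converged,
                 iterations = fit$iterations,
                 fit_decision_values = as.numeric(fit$decision_values)),
            class = "hm_model")
}

#' @export
print.hm_model <- function(x, ...) {
  cat(sprintf("<linear SVM: %d weighted features, bias %.4g, C %.4g, W-1 %.4g%s>\n",
              sum(x$weights != 0), x$bias, x$C, x$negative_class_weight,
              if (isTRUE(x$converged)) "" else ", NOT CONVERGED"))
  invisible(x)
}

check_config <- function(model, fp) {
  if (model$depth != fp$depth || model$hash_bits != fp$hash_bits)
    stop_data(sprintf(
      "fingerprint config (depth %d, %d-bit) incompatible with model (depth %d, %d-bit)",
      fp$depth, fp$hash_bits, model$depth, model$hash_bits))
  invisible(TRUE)
}

#' Prediction (decision) value of a fingerprint under a model
#'
#' For binary fingerprints this is the bias plus the sum of the weights of
#' the present features; its sign is the predicted class and its magnitude
#' a confidence proxy. Features unknown to the model contribute 0.
#'
#' @param model an `hm_model`.
#' @param fp an `hm_fp` made with the model's fingerprint configuration.
#' @return a numeric scalar f(x).
#' @export
decision_value <- function(model, fp) {
  check_config(model, fp)
  keys <- fid_key(fp$features)
  w <- model$weights[keys[keys %in% names(model$weights)]]
  model$bias + sum(w)
}

#' Select C and the negative class weight by inner 2-fold search
#'
#' Scans the (C, W-1) grid, scoring each point by mean AUC over a fixed
#' stratified 2-fold split of `data`. Ties are broken toward the smaller C,
#' then the smaller class weight (simpler models first). Default grids are
#' log2(C) in -5..8 and log2(W-1) in \{-4, -2, 0\}.
#'
#' @param data an `hm_dataset`.
#' @param C_grid candidate C values.
#' @param W_grid candidate negative-class weights.
#' @param seed seed for the inner fold split and the solver.
#' @param folds number of inner folds (default 2).
#' @return list with `C`, `negative_class_weight`, `auc`, and the full
#'   `grid` data.frame.
#' @export
select_hyperparameters <- function(data, C_grid = 2^(-5:8),
                                   W_grid = 2^c(-4, -2, 0), seed = 1L,
                                   folds = 2L) {
  fold <- stratified_folds(data$labels, folds, seed)
  grid <- expand.grid(C = sort(C_grid), W = sort(W_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$W), ]
  grid$auc <- NA_real_
  splits <- lapply(seq_len(folds), function(k)
    list(train = which(fold != k), test = which(fold == k)))
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(splits, function(sp) {
      m <- suppressWarnings(train_linear_svm(
        dataset_subset(data, sp$train), C = grid$C[g],
        negative_class_weight = grid$W[g], seed = seed))
      sc <- vapply(data$fps[sp$test], function(f) decision_value(m, f),
                   numeric(1))
      auc_score(sc, data$labels[sp$test])
    }, numeric(1))
    grid$auc[g] <- mean(aucs)
  }
  best <- which.max(grid$auc)  # first max in (C, W) order = tie-break
  list(C = grid$C[best], negative_class_weight = grid$W[best],
       auc = grid$auc[best], grid = grid)
}

#' Repeated two-deep (nested) cross-validation
#'
#' Outer stratified k-fold, repeated; within each outer training portion
#' the rare-feature filter is fit and the hyperparameters are chosen by
#' [select_hyperparameters()] (inner 2-fold), so the held-out fold never
#' leaks into filtering or model selection. Defaults: 5 outer folds,
#' 2 repeats.
#'
#' @param data an `hm_dataset`.
#' @param folds outer folds (>= 2).
#' @param repeats number of outer repetitions.
#' @param seed integer seed controlling all fold splits and solver order.
#' @param C_grid,W_grid hyperparameter grids.
#' @param min_count rare-feature cutoff fit on each outer training portion.
#' @param keep_models keep the per-fold models (for diagnostics).
#' @return an `hm_eval`: data.frame `folds` (repeat, fold, C, W, auc, acc)
#'   plus `mean_auc`, `mean_acc`.
#' @export
evaluate_cv <- function(data, folds = 5L, repeats = 2L, seed = 1L,
                        C_grid = 2^(-5:8), W_grid = 2^c(-4, -2, 0),
                        min_count = 3L, keep_models = FALSE) {
  stopifnot(folds >= 2)
  res <- list()
  models <- list()
  assignments <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- stratified_folds(data$labels, folds,
                             seed = seed * 1000L + rep_i)
    assignments[[rep_i]] <- fold
    for (k in seq_len(folds)) {
      tr <- which(fold != k)
      te <- which(fold == k)
      if (length(unique(data$labels[te])) < 2)
        stop_data("outer fold lost a class; reduce folds")
      dtr <- filter_rare_features(dataset_subset(data, tr), min_count)
      hp <- select_hyperparameters(dtr, C_grid, W_grid,
                                   seed = seed * 1000L + rep_i * 10L + k)
      m <- suppressWarnings(train_linear_svm(
        dtr, C = hp$C, negative_class_weight = hp$negative_class_weight,
        seed = seed))
      sc <- vapply(data$fps[te], function(f) decision_value(m, f),
                   numeric(1))
      pred <- ifelse(sc >= 0, 1L, -1L)
      res[[length(res) + 1L]] <- data.frame(
        repeat_ = rep_i, fold = k, C = hp$C,
        negative_class_weight = hp$negative_class_weight,
        auc = auc_score(sc, data$labels[te]),
        acc = mean(pred == data$labels[te]))
      if (keep_models) models[[length(models) + 1L]] <- m
    }
  }
  df <- do.call(rbind, res)
  structure(list(folds = df, mean_auc = mean(df$auc),
                 mean_acc = mean(df$acc),
                 assignments = assignments,
                 models = if (keep_models) models else NULL),
            class = "hm_eval")
}

#' @export
print.hm_eval <- function(x, ...) {
  cat(sprintf("<cross-validation: %d fold evaluations, mean AUC %.3f, mean ACC %.3f>\n",
              nrow(x$folds), x$mean_auc, x$mean_acc))
  invisible(x)
}

#' Persist / restore a linear model
#'
#' Versioned plain-text JSON holding weights, bias, hyperparameters and the
#' fingerprint configuration; a loaded model refuses fingerprints made with
#' a different configuration.
#'
#' @param model an `hm_model`.
#' @param path file path.
#' @return `load_model` returns the restored `hm_model`.
#' @export
save_model <- function(model, path) {
  doc <- list(format = "svmheatmap-model", version = 1L,
              weights = as.list(model$weights), bias = model$bias,
              C = model$C,
              negative_class_weight = model$negative_class_weight,
              depth = model$depth, hash_bits = model$hash_bits,
              min_count = model$min_count, converged = model$converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_data(paste("cannot parse model file:",
                                    conditionMessage(e))))
  need <- c("format", "version", "weights", "bias", "depth", "hash_bits")
  if (!all(need %in% names(doc)) ||
      !identical(doc$format, "svmheatmap-model"))
    stop_data("not a svmheatmap model file")
  structure(list(weights = setNames(vapply(doc$weights, as.numeric,
                                           numeric(1)),
                                    names(doc$weights)),
                 bias = as.numeric(doc$bias),
                 C = as.numeric(doc$C %||% NA_real_),
                 negative_class_weight =
                   as.numeric(doc$negative_class_weight %||% NA_real_),
                 depth = as.integer(doc$depth),
                 hash_bits = as.integer(doc$hash_bits),
                 min_count = doc$min_count,
                 converged = isTRUE(doc$converged)),
            class = "hm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
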