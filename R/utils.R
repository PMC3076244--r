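# internal helpers shared across modules

# stable string key for a (possibly > 2^31) numeric feature id
fid_key <- function(id) sprintf("%.0f", id)

# condition helpers: usage errors (bad invocation) vs data errors
stop_usage <- function(msg, call. = FALSE) {
  stop(structure(class = c("hm_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_data <- function(msg) {
  stop(structure(class = c("hm_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param scores numeric prediction values, larger = more active.
#' @param labels vector in \{-1, +1\}.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1L, 1L)))
  np <- sum(labels == 1L)
  nn <- sum(labels == -1L)
  if (np == 0L || nn == 0L) stop_data("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

# stratified fold assignment; returns integer vector of fold ids 1..k
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(1L, -1L)) {
      ix <- which(labels == cls)
      if (length(ix) < k)
        stop_data(sprintf("class %+d has %d members, fewer than %d folds",
                          cls, length(ix), k))
      fold[ix] <- rep_len(seq_len(k), length(ix))[sample.int(length(ix))]
    }
  })
  fold
}

# round half away from zero (printer's rounding for color channels)
round_half_up <- function(x) floor(x + 0.5)

rgb_hex <- function(rgb) {
  rgb <- matrix(as.integer(rgb), ncol = 3)
  sprintf("#%02X%02X%02X", rgb[, 1], rgb[, 2], rgb[, 3])
}
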