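# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Stratified fold assignment: within each class, shuffle and deal
# round-robin so fold sizes differ by at most one per class.  Classes are
# visited in first-appearance order so fold membership depends on the class
# partition, not on what the labels are called.
stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  if (folds < 2) stop("folds must be at least 2")
  if (min(table(y)) < folds) {
    stop("a class has fewer samples than folds; cannot stratify")
  }
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

misclassification <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  mean(as.character(predicted) != as.character(truth))
}
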