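#' Biological effects ("virtual samples")
#'
#' Per-sample expression profiles taken from the uniformly handled dataset,
#' interpreted as each sample's biological effect.  Columns are indexed by
#' sample ID and annotated with the binary class label.
#'
#' @param values Numeric matrix, probe rows x samples, log2 scale.
#' @param class_labels Character vector of class labels named by sample ID,
#'   or unnamed in column order.
#' @return A `biological_effects` object.
#' @export
biological_effects <- function(values, class_labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs probe rownames and sample colnames")
  }
  if (is.null(names(class_labels))) names(class_labels) <- colnames(values)
  class_labels <- class_labels[colnames(values)]
  if (anyNA(class_labels)) stop("every sample needs a class label")
  structure(list(values = values,
                 class_labels = stats::setNames(as.character(class_labels),
                                                colnames(values))),
            class = "biological_effects")
}

#' @export
print.biological_effects <- function(x, ...) {
  cat(sprintf("biological_effects: %d probe rows x %d virtual samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$class_labels),
                            names(table(x$class_labels))), collapse = " + ")))
  invisible(x)
}

#' Handling effects ("virtual arrays")
#'
#' Per-array handling-effect profiles on the log2-difference scale, each the
#' paired difference between a sample's non-uniformly handled array and its
#' uniformly handled one.  Carries processing order and batch per array.
#'
#' @param values Numeric matrix, probe rows x arrays.
#' @param processing_order Integer rank per array (named or in column order).
#' @param batch Batch label per array.
#' @return A `handling_effects` object.
#' @export
handling_effects <- function(values, processing_order, batch) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs probe rownames and array colnames")
  }
  if (is.null(names(processing_order))) names(processing_order) <- colnames(values)
  if (is.null(names(batch))) names(batch) <- colnames(values)
  processing_order <- processing_order[colnames(values)]
  batch <- batch[colnames(values)]
  if (anyNA(processing_order)) stop("every array needs a processing order")
  structure(list(values = values,
                 processing_order = stats::setNames(
                   as.integer(processing_order), colnames(values)),
                 batch = stats::setNames(as.character(batch),
                                         colnames(values))),
            class = "handling_effects")
}

#' @export
print.handling_effects <- function(x, ...) {
  cat(sprintf("handling_effects: %d probe rows x %d virtual arrays, %d batch(es)\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch))))
  invisible(x)
}

#' Estimate biological effects from the uniformly handled dataset
#'
#' The uniformly handled dataset is taken as the biological truth: each of
#' its per-sample profiles becomes that sample's "virtual sample".
#'
#' @param study A log2-scale [paired_study()].
#' @return A [biological_effects()] object with one column per sample.
#' @export
estimate_biological_effects <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  if (study$uniform$scale != "log2") {
    stop("log2-transform the study first (study_log2)")
  }
  miss <- setdiff(study$samples$sample_id, array_ids(study$uniform))
  if (length(miss) > 0) {
    stop("annotated samples missing from uniform matrix: ",
         paste(miss, collapse = ", "))
  }
  v <- study$uniform$values[, study$samples$sample_id, drop = FALSE]
  biological_effects(v, stats::setNames(study$samples$class,
                                        study$samples$sample_id))
}

#' Estimate handling effects as paired array differences
#'
#' For each sample, the difference between its non-uniformly handled array
#' and its uniformly handled array estimates the handling effect of that
#' array — its "virtual array".  The decomposition is lossless: uniform
#' profile + handling column reconstructs the non-uniform profile exactly.
#'
#' @param study A log2-scale [paired_study()].
#' @return A [handling_effects()] object with one column per non-uniform
#'   array, in annotation order.
#' @export
estimate_handling_effects <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  if (study$uniform$scale != "log2" || study$nonuniform$scale != "log2") {
    stop("log2-transform the study first (study_log2)")
  }
  s2a <- study$sample_to_array
  miss_s <- setdiff(names(s2a), array_ids(study$uniform))
  miss_a <- setdiff(s2a, array_ids(study$nonuniform))
  if (length(miss_s) > 0 || length(miss_a) > 0) {
    stop("unmatched samples/arrays: ",
         paste(c(miss_s, miss_a), collapse = ", "))
  }
  a2s <- stats::setNames(names(s2a), s2a)
  ord_arrays <- study$arrays$array_id
  diffs <- study$nonuniform$values[, ord_arrays, drop = FALSE] -
    study$uniform$values[, a2s[ord_arrays], drop = FALSE]
  colnames(diffs) <- ord_arrays
  handling_effects(diffs,
                   stats::setNames(study$arrays$processing_order,
                                   study$arrays$array_id),
                   stats::setNames(study$arrays$batch, study$arrays$array_id))
}

#' Shrink the biological class signal
#'
#' Signal-to-noise dial: for each selected probe row, every sample's value
#' moves toward the midpoint of the two class means so that the
#' between-class mean difference becomes `factor` times the original, while
#' within-class deviations around the class mean are untouched.
#' `factor = 1` is the identity; `factor = 0` equalizes the class means.
#'
#' @param bio A [biological_effects()] object.
#' @param factor Real in `[0, 1]`.
#' @param probes Optional subset of probe IDs to shrink (default all rows).
#' @return The adjusted `biological_effects`.
#' @export
reduce_signal <- function(bio, factor, probes = NULL) {
  stopifnot(inherits(bio, "biological_effects"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0 || factor > 1) {
    stop("factor must be a single value in [0, 1]")
  }
  rows <- if (is.null(probes)) seq_len(nrow(bio$values)) else {
    unknown <- setdiff(probes, rownames(bio$values))
    if (length(unknown) > 0) {
      stop("unknown probe IDs: ", paste(unknown, collapse = ", "))
    }
    which(rownames(bio$values) %in% probes)
  }
  cls <- bio$class_labels
  lv <- sort(unique(cls))
  m1 <- rowMeans(bio$values[rows, cls == lv[1], drop = FALSE])
  m2 <- rowMeans(bio$values[rows, cls == lv[2], drop = FALSE])
  mid <- (m1 + m2) / 2
  shift <- cbind(m1 - mid, m2 - mid)[, match(cls, lv), drop = FALSE]
  bio$values[rows, ] <- bio$values[rows, , drop = FALSE] - (1 - factor) * shift
  bio
}

#' Amplify (or mute) handling effects
#'
#' Signal-to-noise dial: selected virtual-array columns are multiplied
#' elementwise by `factor`; no re-centering.  `factor = 0` removes handling
#' effects entirely, `factor > 1` exaggerates them.
#'
#' @param handling A [handling_effects()] object.
#' @param factor Real `>= 0`.
#' @param arrays Optional subset of array IDs to scale (default all).
#' @return The adjusted `handling_effects`.
#' @export
amplify_handling_effects <- function(handling, factor, arrays = NULL) {
  stopifnot(inherits(handling, "handling_effects"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 0) {
    stop("factor must be a single nonnegative value")
  }
  cols <- if (is.null(arrays)) seq_len(ncol(handling$values)) else {
    unknown <- setdiff(arrays, colnames(handling$values))
    if (length(unknown) > 0) {
      stop("unknown array IDs: ", paste(unknown, collapse = ", "))
    }
    which(colnames(handling$values) %in% arrays)
  }
  handling$values[, cols] <- handling$values[, cols, drop = FALSE] * factor
  handling
}
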