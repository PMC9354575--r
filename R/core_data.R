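#' Expression matrix with probe-replicate structure
#'
#' A probes x arrays intensity matrix.  Probe identifiers may repeat: rows
#' sharing an identifier are replicate probes for the same microRNA and are
#' later collapsed by [summarize_probe_replicates()].  Array identifiers are
#' unique.  The object carries a scale flag so that the log2 transformation
#' cannot be applied twice.
#'
#' @param values Numeric matrix, probes in rows, arrays in columns.
#' @param probe_ids Character vector of probe identifiers, one per row.
#'   Defaults to `rownames(values)`.  Duplicates denote probe replicates.
#' @param array_ids Character vector of unique array identifiers, one per
#'   column.  Defaults to `colnames(values)`.
#' @param scale Either `"raw"` (fluorescence intensities, strictly positive)
#'   or `"log2"`.
#' @return An object of class `expression_matrix`.
#' @seealso [load_expression_matrix()], [log2_transform()],
#'   [summarize_probe_replicates()]
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              array_ids = colnames(values),
                              scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(array_ids)) {
    stop("probe_ids and array_ids are required (as arguments or dimnames)")
  }
  probe_ids <- as.character(probe_ids)
  array_ids <- as.character(array_ids)
  rownames(values) <- probe_ids
  colnames(values) <- array_ids
  x <- structure(list(values = values, scale = scale),
                 class = "expression_matrix")
  validate_expression_matrix(x)
  x
}

validate_expression_matrix <- function(x) {
  v <- x$values
  if (nrow(v) != length(rownames(v)) || ncol(v) != length(colnames(v))) {
    stop("dimnames do not match matrix dimensions")
  }
  if (anyDuplicated(colnames(v))) {
    dup <- unique(colnames(v)[duplicated(colnames(v))])
    stop("duplicate array IDs: ", paste(dup, collapse = ", "))
  }
  if (anyNA(v)) stop("missing values are not allowed in an expression matrix")
  if (x$scale == "raw" && any(v <= 0)) {
    stop("raw-scale intensities must be strictly positive")
  }
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probe rows (%d unique IDs) x %d arrays, scale=%s\n",
              nrow(x$values), length(unique(probe_ids(x))), ncol(x$values),
              x$scale))
  invisible(x)
}

#' Probe and array identifiers
#'
#' Accessors for the row (probe) and column (array) identifiers of an
#' [expression_matrix()].
#'
#' @param x An `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname probe_ids
#' @export
array_ids <- function(x) colnames(x$values)

#' @export
dim.expression_matrix <- function(x) dim(x$values)

infer_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from a delimited file
#'
#' Expects a header row of unique array identifiers and a first column of
#' probe identifiers; the body must be numeric and, being raw fluorescence,
#' strictly positive.  The delimiter is inferred from the extension
#' (`.csv` is comma, everything else tab) unless given explicitly.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter; `NULL` (default) infers from the extension.
#' @return An [expression_matrix()] with `scale = "raw"`.
#' @export
load_expression_matrix <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("expected a probe-ID column plus at least one array column")
  probe <- trimws(tab[[1]])
  body <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at probe '%s', array '%s'",
                   body[bad[1, 1], bad[1, 2]], probe[bad[1, 1]],
                   colnames(tab)[-1][bad[1, 2]]))
    }
    stop("missing values in expression matrix file")
  }
  expression_matrix(num, probe_ids = probe, array_ids = colnames(tab)[-1],
                    scale = "raw")
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [load_expression_matrix()]: first column `probe_id`, header of
#' array identifiers, full numeric precision.
#'
#' @param x An `expression_matrix`.
#' @param path Output file path.
#' @param sep Field delimiter; `NULL` infers from the extension.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- data.frame(probe_id = probe_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform raw intensities
#'
#' First preprocessing step: every raw fluorescence value is replaced by its
#' base-2 logarithm.  Guarded so it cannot run twice.
#'
#' @param x An `expression_matrix` with `scale = "raw"`.
#' @return The log2-scale `expression_matrix`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale == "log2") stop("matrix is already on the log2 scale")
  if (any(x$values <= 0)) stop("log2 transform requires strictly positive values")
  expression_matrix(log2(x$values), scale = "log2")
}

#' Collapse probe replicates by the median
#'
#' Rows sharing a probe identifier (after whitespace trimming) are replicate
#' probes; per array they collapse to their median.  Even-sized replicate
#' sets use the midpoint of the two central order statistics.  Output rows
#' keep the first-appearance order of each identifier, so the operation is
#' idempotent.
#'
#' @param x A log2-scale `expression_matrix`.
#' @return An `expression_matrix` with unique probe identifiers.
#' @export
summarize_probe_replicates <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "log2") stop("summarization expects log2-scale data")
  ids <- trimws(probe_ids(x))
  lev <- unique(ids)
  groups <- split(seq_along(ids), factor(ids, levels = lev))
  out <- t(vapply(groups, function(i) {
    apply(x$values[i, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(x$values))))
  expression_matrix(out, probe_ids = lev, array_ids = array_ids(x),
                    scale = "log2")
}

#' Sample annotation
#'
#' Binary class labels (the classification endpoint, e.g. endometrial versus
#' ovarian tumor type) for a set of uniquely identified samples.
#'
#' @param sample_ids Unique sample identifiers.
#' @param class_labels One label per sample; exactly two distinct values.
#' @return A `sample_annotation` data frame with columns `sample_id`, `class`.
#' @export
sample_annotation <- function(sample_ids, class_labels) {
  sample_ids <- as.character(sample_ids)
  class_labels <- as.character(class_labels)
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  if (length(class_labels) != length(sample_ids)) {
    stop("one class label per sample is required")
  }
  if (length(unique(class_labels)) != 2) {
    stop("class labels must take exactly two distinct values")
  }
  structure(data.frame(sample_id = sample_ids, class = class_labels,
                       stringsAsFactors = FALSE),
            class = c("sample_annotation", "data.frame"))
}

#' Array annotation
#'
#' Processing order (the rank in which arrays were physically handled) and
#' batch (e.g. technician or run) for each array of the non-uniformly
#' handled dataset.
#'
#' @param array_ids Unique array identifiers.
#' @param processing_order Integer ranks; must be a permutation of
#'   `1:length(array_ids)`.
#' @param batch Categorical batch label per array.
#' @return An `array_annotation` data frame.
#' @export
array_annotation <- function(array_ids, processing_order, batch) {
  array_ids <- as.character(array_ids)
  if (anyDuplicated(array_ids)) stop("array IDs must be unique")
  processing_order <- as.integer(processing_order)
  if (!setequal(processing_order, seq_along(array_ids)) ||
      anyDuplicated(processing_order)) {
    stop("processing_order must be a permutation of 1..n")
  }
  structure(data.frame(array_id = array_ids,
                       processing_order = processing_order,
                       batch = as.character(batch),
                       stringsAsFactors = FALSE),
            class = c("array_annotation", "data.frame"))
}

#' Read sample / array annotation tables
#'
#' Tab-delimited files with columns (`sample_id`, `class`) and
#' (`array_id`, `processing_order`, `batch`) respectively.
#'
#' @param path Path to a TSV file.
#' @return A validated annotation object.
#' @export
load_sample_annotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(tab))) {
    stop("sample annotation needs columns sample_id, class")
  }
  sample_annotation(tab$sample_id, tab$class)
}

#' @rdname load_sample_annotation
#' @export
load_array_annotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (!all(c("array_id", "processing_order", "batch") %in% names(tab))) {
    stop("array annotation needs columns array_id, processing_order, batch")
  }
  array_annotation(tab$array_id, as.integer(tab$processing_order), tab$batch)
}

#' Paired study: the same samples profiled twice
#'
#' Couples a uniformly handled expression matrix with a non-uniformly
#' handled one over the same samples.  The uniform matrix's columns are
#' indexed directly by sample ID (uniform handling, identity assignment);
#' the non-uniform matrix's columns are array IDs described by an
#' [array_annotation()], and `sample_to_array` declares the one-to-one
#' sample-to-array correspondence.
#'
#' @param uniform,nonuniform `expression_matrix` objects with identical
#'   probe IDs in identical order.
#' @param samples A [sample_annotation()].
#' @param arrays An [array_annotation()] describing the non-uniform arrays.
#' @param sample_to_array Named character vector: names are sample IDs,
#'   values are the matched non-uniform array IDs.  Defaults to matching by
#'   position.
#' @return A `paired_study` object.
#' @export
paired_study <- function(uniform, nonuniform, samples, arrays,
                         sample_to_array = NULL) {
  stopifnot(inherits(uniform, "expression_matrix"),
            inherits(nonuniform, "expression_matrix"),
            inherits(samples, "sample_annotation"),
            inherits(arrays, "array_annotation"))
  if (!identical(probe_ids(uniform), probe_ids(nonuniform))) {
    stop("uniform and nonuniform matrices must share probe IDs in the same order")
  }
  if (!identical(uniform$scale, nonuniform$scale)) {
    stop("uniform and nonuniform matrices must share the same scale")
  }
  if (!setequal(array_ids(uniform), samples$sample_id)) {
    stop("uniform matrix columns must be the annotated sample IDs")
  }
  if (!setequal(array_ids(nonuniform), arrays$array_id)) {
    stop("nonuniform matrix columns must be the annotated array IDs")
  }
  if (is.null(sample_to_array)) {
    sample_to_array <- stats::setNames(arrays$array_id, samples$sample_id)
  }
  if (!setequal(names(sample_to_array), samples$sample_id) ||
      !setequal(sample_to_array, arrays$array_id) ||
      anyDuplicated(sample_to_array)) {
    stop("sample_to_array must be a bijection from sample IDs to array IDs")
  }
  structure(list(uniform = uniform, nonuniform = nonuniform,
                 samples = samples, arrays = arrays,
                 sample_to_array = sample_to_array),
            class = "paired_study")
}

#' @export
print.paired_study <- function(x, ...) {
  cat(sprintf("paired_study: %d samples (%s), %d probe rows, scale=%s\n",
              nrow(x$samples),
              paste(sprintf("%d %s", table(x$samples$class),
                            names(table(x$samples$class))), collapse = " + "),
              nrow(x$uniform$values), x$uniform$scale))
  invisible(x)
}

#' Log2-transform both matrices of a paired study
#'
#' @param study A raw-scale `paired_study`.
#' @return The study with both matrices log2-transformed.
#' @export
study_log2 <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  study$uniform <- log2_transform(study$uniform)
  study$nonuniform <- log2_transform(study$nonuniform)
  study
}
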