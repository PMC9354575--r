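#' Train/test split of virtual samples and virtual arrays
#'
#' Virtual samples are split randomly, stratified by class, in a 2:1
#' train:test ratio.  Virtual arrays are split deterministically by
#' processing order: the first and last thirds go to the training set and
#' the middle third to the test set (at the original study scale of 192
#' arrays: first 64 + last 64 train, middle 64 test).
#'
#' @param bio A [biological_effects()] object.
#' @param handling A [handling_effects()] object.
#' @param seed Integer seed for the random sample split.
#' @return A `study_split` with `train_sample_ids`, `test_sample_ids`,
#'   `train_array_ids`, `test_array_ids`.
#' @export
split_study <- function(bio, handling, seed) {
  stopifnot(inherits(bio, "biological_effects"),
            inherits(handling, "handling_effects"))
  n_arrays <- ncol(handling$values)
  if (n_arrays %% 3 != 0) {
    stop("array count must be divisible by 3 for the thirds split (got ",
         n_arrays, ")")
  }
  smp <- split_samples(bio$class_labels, seed)
  ord <- colnames(handling$values)[order(handling$processing_order)]
  third <- n_arrays / 3
  test_arrays <- ord[(third + 1):(2 * third)]
  train_arrays <- c(ord[1:third], ord[(2 * third + 1):n_arrays])
  structure(list(train_sample_ids = smp$train,
                 test_sample_ids = smp$test,
                 train_array_ids = train_arrays,
                 test_array_ids = test_arrays),
            class = "study_split")
}

# Class-stratified random 2:1 sample split (seeded).  Requires each class
# size to be divisible by 3 so the ratio is exact.
split_samples <- function(class_labels, seed) {
  ids <- names(class_labels)
  stopifnot(!is.null(ids))
  train <- character(0)
  with_seed(seed, {
    for (cl in sort(unique(class_labels))) {
      members <- ids[class_labels == cl]
      if (length(members) %% 3 != 0) {
        stop("class '", cl, "' has ", length(members),
             " samples; each class size must be divisible by 3 for a 2:1 split")
      }
      train <- c(train, sample(members, 2 * length(members) / 3))
    }
  })
  train <- ids[ids %in% train]            # restore annotation order
  list(train = train, test = setdiff(ids, train))
}

#' Assign arrays to samples under a study design
#'
#' Builds the bijective array-to-sample mapping for one split part.
#' Designs:
#' \describe{
#'   \item{confounding}{arrays in ascending processing order go to all
#'     samples of the first class (sorted label order) first, then the
#'     second; within-class order is randomized by `seed`.  Class and
#'     processing order become perfectly aligned.}
#'   \item{balanced}{arrays are cut into consecutive processing-order
#'     blocks of `block_size`; each block receives an equal number of
#'     samples from each class, placed randomly within the block.}
#'   \item{complete_random}{a uniformly random bijection.}
#' }
#'
#' @param sample_ids Sample identifiers of the part.
#' @param class_labels Class label per sample (named by, or ordered as,
#'   `sample_ids`).
#' @param array_ids Array identifiers of the part.
#' @param processing_order Processing rank per array.
#' @param design One of `"confounding"`, `"balanced"`, `"complete_random"`.
#' @param seed Integer seed.
#' @param block_size Even block length for the balanced design; the default
#'   `2 * ceiling(n / 48)` gives blocks of 8 at the original 192-array study
#'   scale and scales down proportionally for small fixtures.
#' @return A `design_assignment`: data frame (`array_id`, `sample_id`) with
#'   attributes `design_name` and `seed`.
#' @export
assign_arrays <- function(sample_ids, class_labels, array_ids,
                          processing_order,
                          design = c("confounding", "balanced",
                                     "complete_random"),
                          seed = 1L, block_size = NULL) {
  design <- match.arg(design)
  sample_ids <- as.character(sample_ids)
  array_ids <- as.character(array_ids)
  if (length(sample_ids) != length(array_ids)) {
    stop("need exactly as many arrays as samples (got ",
         length(array_ids), " vs ", length(sample_ids), ")")
  }
  if (is.null(names(class_labels))) names(class_labels) <- sample_ids
  class_labels <- as.character(class_labels[sample_ids])
  ord_arrays <- array_ids[order(processing_order)]
  n <- length(sample_ids)
  classes <- sort(unique(class_labels))

  assigned <- switch(design,
    confounding = with_seed(seed, {
      unlist(lapply(classes, function(cl) {
        sample(sample_ids[class_labels == cl])
      }), use.names = FALSE)
    }),
    balanced = {
      if (is.null(block_size)) block_size <- 2L * as.integer(ceiling(n / 48))
      if (block_size %% 2 != 0 || block_size < 2) {
        stop("block_size must be even and >= 2")
      }
      if (n %% block_size != 0) {
        stop("block_size (", block_size, ") must divide the number of arrays (",
             n, ")")
      }
      counts <- table(factor(class_labels, levels = classes))
      if (length(unique(as.integer(counts))) != 1) {
        stop("balanced design requires equal class counts (got ",
             paste(counts, collapse = " vs "), ")")
      }
      per_class <- block_size / length(classes)
      if (per_class != floor(per_class)) {
        stop("block_size must be a multiple of the number of classes")
      }
      n_blocks <- n / block_size
      if (any(counts < per_class * n_blocks)) {
        stop("class counts cannot fill every block equally")
      }
      with_seed(seed, {
        queues <- lapply(classes, function(cl) {
          sample(sample_ids[class_labels == cl])
        })
        out <- character(0)
        for (b in seq_len(n_blocks)) {
          take <- unlist(lapply(seq_along(classes), function(k) {
            queues[[k]][(b - 1) * per_class + seq_len(per_class)]
          }), use.names = FALSE)
          out <- c(out, sample(take))
        }
        out
      })
    },
    complete_random = with_seed(seed, sample(sample_ids))
  )

  structure(data.frame(array_id = ord_arrays, sample_id = assigned,
                       stringsAsFactors = FALSE),
            design_name = design, seed = as.integer(seed),
            class = c("design_assignment", "data.frame"))
}

#' Write / read a design assignment as TSV
#'
#' Two columns (`array_id`, `sample_id`) preceded by header comments
#' recording the design name and seed.
#'
#' @param assignment A `design_assignment`.
#' @param path Output path.
#' @return `path` invisibly (write) or the `design_assignment` (read).
#' @export
write_design_assignment <- function(assignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# design_name=", attr(assignment, "design_name")),
               paste0("# seed=", attr(assignment, "seed"))), con)
  utils::write.table(assignment, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_assignment
#' @export
load_design_assignment <- function(path) {
  header <- readLines(path, n = 2)
  design <- sub("^# design_name=", "", header[1])
  seed <- as.integer(sub("^# seed=", "", header[2]))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           colClasses = "character")
  structure(data.frame(array_id = tab$array_id, sample_id = tab$sample_id,
                       stringsAsFactors = FALSE),
            design_name = design, seed = seed,
            class = c("design_assignment", "data.frame"))
}

#' Virtual re-hybridization
#'
#' Simulates a dataset by summing, for each sample, its biological effect
#' column and the handling-effect column of the array assigned to it.
#' Output columns follow the order of the samples in `bio` (restricted to
#' the assignment) and are labeled by sample ID; the assigned array per
#' sample is retained as the `"assigned_array"` attribute.
#'
#' @param bio A [biological_effects()] object.
#' @param handling A [handling_effects()] object with identical probe rows.
#' @param assignment A `design_assignment` from [assign_arrays()].
#' @return A log2-scale [expression_matrix()], one column per assigned
#'   sample.
#' @export
rehybridize <- function(bio, handling, assignment) {
  stopifnot(inherits(bio, "biological_effects"),
            inherits(handling, "handling_effects"),
            inherits(assignment, "design_assignment"))
  if (!identical(rownames(bio$values), rownames(handling$values))) {
    stop("bio and handling probe IDs must be identical and in the same order")
  }
  miss_s <- setdiff(assignment$sample_id, colnames(bio$values))
  miss_a <- setdiff(assignment$array_id, colnames(handling$values))
  if (length(miss_s) > 0 || length(miss_a) > 0) {
    stop("assignment refers to unknown samples/arrays: ",
         paste(c(miss_s, miss_a), collapse = ", "))
  }
  samples <- colnames(bio$values)[colnames(bio$values) %in% assignment$sample_id]
  arr_of <- stats::setNames(assignment$array_id, assignment$sample_id)[samples]
  v <- bio$values[, samples, drop = FALSE] +
    handling$values[, arr_of, drop = FALSE]
  colnames(v) <- samples
  out <- expression_matrix(v, scale = "log2")
  attr(out, "assigned_array") <- arr_of
  out
}

#' Benchmark (handling-free) test data
#'
#' The test-set biological effects with no handling effects added: the
#' yardstick against which classifier accuracy is judged.
#'
#' @param bio A [biological_effects()] object.
#' @param split A `study_split` from [split_study()].
#' @return A log2-scale [expression_matrix()] over the test samples.
#' @export
make_benchmark <- function(bio, split) {
  stopifnot(inherits(bio, "biological_effects"),
            inherits(split, "study_split"))
  keep <- colnames(bio$values)[colnames(bio$values) %in% split$test_sample_ids]
  expression_matrix(bio$values[, keep, drop = FALSE], scale = "log2")
}
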