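#' Simulation grid configuration
#'
#' Bundles every knob of the assessment grid: repetitions and base seed,
#' the array-to-sample designs for the training and test parts, the two
#' signal-to-noise dials, and the lists of normalization strategies and
#' classifiers to cross.  All list entries are validated against the
#' registries up front, so an invalid name fails before any computation.
#'
#' @param n_repetitions Number of simulation repetitions (default 20).
#' @param base_seed Integer; repetition r uses seeds derived from
#'   `base_seed + r`.
#' @param train_design,test_design Design names for [assign_arrays()]
#'   (may differ between parts).
#' @param signal_factor Biological-signal dial for [reduce_signal()]
#'   (default 1, untouched).
#' @param handling_factor Handling-effect dial for
#'   [amplify_handling_effects()] (default 1).
#' @param train_norms Subset of `c("none", train_normalizations())`.
#' @param test_norms Subset of `c("none", test_normalizations())`.
#' @param classifiers Subset of [classifier_methods()].
#' @param block_size Block length for the balanced design (`NULL` =
#'   default of [assign_arrays()]).
#' @param folds Cross-validation folds (default 5).
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_repetitions = 20, base_seed = 1L,
                              train_design = "balanced",
                              test_design = "balanced",
                              signal_factor = 1, handling_factor = 1,
                              train_norms = c("none", "median", "quantile"),
                              test_norms = c("none", "median_frozen",
                                             "quantile_frozen",
                                             "pooled_quantile"),
                              classifiers = c("dlda", "pam"),
                              block_size = NULL, folds = 5) {
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  designs <- c("confounding", "balanced", "complete_random")
  if (!train_design %in% designs || !test_design %in% designs) {
    stop("designs must be one of: ", paste(designs, collapse = ", "))
  }
  bad <- setdiff(train_norms, c("none", train_normalizations()))
  if (length(bad) > 0) stop("unknown training normalization: ",
                            paste(bad, collapse = ", "))
  bad <- setdiff(test_norms, c("none", test_normalizations()))
  if (length(bad) > 0) stop("unknown test normalization: ",
                            paste(bad, collapse = ", "))
  bad <- setdiff(classifiers, classifier_methods())
  if (length(bad) > 0) stop("unknown classifier: ", paste(bad, collapse = ", "))
  structure(list(n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed),
                 train_design = train_design, test_design = test_design,
                 signal_factor = signal_factor,
                 handling_factor = handling_factor,
                 train_norms = train_norms, test_norms = test_norms,
                 classifiers = classifiers, block_size = block_size,
                 folds = as.integer(folds)),
            class = "simulation_config")
}

# A frozen test strategy is only meaningful with the matching training
# normalization; other pairings are recorded as incompatible cells.
frozen_requirement <- c(median_frozen = "median", quantile_frozen = "quantile",
                        vsn_frozen = "vsn")

compatible_pair <- function(train_norm, test_norm) {
  !(test_norm %in% names(frozen_requirement)) ||
    identical(frozen_requirement[[test_norm]], train_norm)
}

validation_targets <- function() {
  c("cross_validation", "external_simulated", "external_benchmark")
}

# Shared engine behind uni_handled_simulate and precision_simulate.  When
# `handling` is NULL the run is handling-free: train/test data are the raw
# biological effects of the split parts, and simulated test == benchmark.
# Seeds: repetition r uses base_seed + r for the sample split, + 1000/2000
# offsets for the train/test array assignment, and per-classifier offsets
# (indexed by registry position, so partial classifier lists reproduce the
# corresponding cells of a full run) for tuning and cross-validation.
run_simulation <- function(config, bio, handling = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(bio, "biological_effects"))
  if (!is.null(handling)) {
    stopifnot(inherits(handling, "handling_effects"))
    if (!identical(rownames(bio$values), rownames(handling$values))) {
      stop("bio and handling probe sets must be identical")
    }
  }
  bio <- reduce_signal(bio, config$signal_factor)
  if (!is.null(handling)) {
    handling <- amplify_handling_effects(handling, config$handling_factor)
  }
  labels <- stats::setNames(bio$class_labels, colnames(bio$values))
  rows <- list()
  for (r in seq_len(config$n_repetitions)) {
    seed_r <- config$base_seed + r
    if (is.null(handling)) {
      smp <- split_samples(labels, seed_r)
      train_ids <- smp$train; test_ids <- smp$test
      x_train <- expression_matrix(bio$values[, train_ids, drop = FALSE],
                                   scale = "log2")
      x_test_sim <- expression_matrix(bio$values[, test_ids, drop = FALSE],
                                      scale = "log2")
      x_test_bench <- x_test_sim
      design_train <- "uniform"; design_test <- "uniform"
    } else {
      split <- split_study(bio, handling, seed_r)
      train_ids <- split$train_sample_ids; test_ids <- split$test_sample_ids
      ord <- stats::setNames(handling$processing_order,
                             colnames(handling$values))
      asg_train <- assign_arrays(
        train_ids, labels[train_ids], split$train_array_ids,
        ord[split$train_array_ids], design = config$train_design,
        seed = seed_r + 1000L, block_size = config$block_size)
      asg_test <- assign_arrays(
        test_ids, labels[test_ids], split$test_array_ids,
        ord[split$test_array_ids], design = config$test_design,
        seed = seed_r + 2000L, block_size = config$block_size)
      x_train <- rehybridize(bio, handling, asg_train)
      x_test_sim <- rehybridize(bio, handling, asg_test)
      x_test_bench <- make_benchmark(bio, split)
      design_train <- config$train_design; design_test <- config$test_design
    }
    y_train <- labels[array_ids(x_train)]
    y_test <- labels[array_ids(x_test_sim)]
    y_bench <- labels[array_ids(x_test_bench)]

    for (tn in config$train_norms) {
      norm <- normalize_train(x_train, tn)
      train_sum <- summarize_probe_replicates(norm$normalized)
      for (clf_name in config$classifiers) {
        clf_seed <- seed_r + 3000L +
          10L * match(clf_name, classifier_methods())
        fit <- tryCatch(
          train_classifier(train_sum$values, y_train, method = clf_name,
                           folds = config$folds, seed = clf_seed),
          error = function(e) e)
        cv <- if (inherits(fit, "error")) NA_real_ else tryCatch(
          cross_validate(train_sum$values, y_train, method = clf_name,
                         folds = config$folds, seed = clf_seed + 5L),
          error = function(e) NA_real_)
        hyper <- if (inherits(fit, "error")) NA_character_ else {
          sel <- fit$tuning_record$selected
          if (length(sel) == 0) "" else
            paste(names(sel), vapply(sel, format, ""), sep = "=",
                  collapse = ";")
        }
        for (sn in config$test_norms) {
          compatible <- compatible_pair(tn, sn)
          ext <- c(external_simulated = NA_real_,
                   external_benchmark = NA_real_)
          status <- if (inherits(fit, "error")) "error"
                    else if (!compatible) "incompatible" else "ok"
          if (status == "ok") {
            ext_one <- function(x_test, y_true) {
              tryCatch({
                tnorm <- normalize_test(x_test, sn, reference = norm$reference,
                                        x_train = x_train)
                external_validate(fit, summarize_probe_replicates(tnorm)$values,
                                  y_true)
              }, error = function(e) NA_real_)
            }
            ext["external_simulated"] <- ext_one(x_test_sim, y_test)
            ext["external_benchmark"] <- ext_one(x_test_bench, y_bench)
            if (anyNA(ext)) status <- "error"
          }
          err_by_target <- c(cross_validation = cv, ext)
          for (tgt in validation_targets()) {
            rows[[length(rows) + 1]] <- data.frame(
              repetition = r, train_design = design_train,
              test_design = design_test, train_norm = tn, test_norm = sn,
              classifier = clf_name, validation = tgt,
              error = unname(err_by_target[tgt]),
              status = if (tgt == "cross_validation" && !is.na(cv)) "ok"
                       else status,
              seed = seed_r, hyperparameters = hyper,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("assessment_result", "data.frame")
  res
}

#' Assess the grid on uniformly handled (handling-free) data
#'
#' Repeats the class-stratified 2:1 sample split and runs the full
#' normalization x classifier x validation grid on biological effects only,
#' with no handling effects and no array assignment.  The external
#' simulated and benchmark validations coincide by construction.
#'
#' @param config A [simulation_config()].
#' @param bio A [biological_effects()] object.
#' @return An `assessment_result` data frame: one row per (repetition,
#'   train_norm, test_norm, classifier, validation target) with the
#'   misclassification proportion, a status flag, and provenance.
#' @export
uni_handled_simulate <- function(config, bio) {
  run_simulation(config, bio, handling = NULL)
}

#' Assess the grid on virtually re-hybridized data
#'
#' The full benchmarking loop: per repetition, split virtual samples (2:1,
#' stratified) and virtual arrays (first/last thirds train, middle third
#' test by processing order), assign arrays to samples under the configured
#' designs, re-hybridize, then cross every training normalization with
#' every test strategy and classifier, scoring by cross-validation, by
#' external validation on the simulated (handling-affected) test set, and
#' by external validation on the handling-free benchmark test set.
#'
#' @inheritParams uni_handled_simulate
#' @param handling A [handling_effects()] object over the same probe rows.
#' @return An `assessment_result` data frame (see
#'   [uni_handled_simulate()]), additionally keyed by the train/test
#'   designs.
#' @export
precision_simulate <- function(config, bio, handling) {
  run_simulation(config, bio, handling = handling)
}

#' Run the full grid across every configured classifier
#'
#' Convenience wrapper: runs [precision_simulate()] separately for each
#' classifier in the configuration and merges the tables.  Because
#' per-classifier seeds are indexed by registry position, the merged table
#' is identical to a single joint run.
#'
#' @inheritParams precision_simulate
#' @return The merged `assessment_result`.
#' @export
precision_simulate_multiclass <- function(config, bio, handling) {
  parts <- lapply(config$classifiers, function(clf) {
    cfg <- config
    cfg$classifiers <- clf
    precision_simulate(cfg, bio, handling)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  class(res) <- c("assessment_result", "data.frame")
  res
}

#' Summarize an assessment grid
#'
#' Mean, SD (0 for a single repetition), and interquartile range of the
#' misclassification proportion per grid cell, plus the difference of each
#' cell's mean against the no-normalization reference cell (same design,
#' classifier, and validation target, `train_norm = test_norm = "none"`).
#'
#' @param result An `assessment_result`.
#' @return A tibble-compatible data frame, one row per grid cell.
#' @export
summarize_results <- function(result) {
  stopifnot(inherits(result, "data.frame"), nrow(result) > 0)
  keys <- c("train_design", "test_design", "train_norm", "test_norm",
            "classifier", "validation")
  summ <- result |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarize(
      n_repetitions = sum(!is.na(.data$error)),
      mean_error = if (any(!is.na(.data$error))) {
        mean(.data$error, na.rm = TRUE)
      } else NA_real_,
      sd_error = if (sum(!is.na(.data$error)) > 1) {
        stats::sd(.data$error, na.rm = TRUE)
      } else 0,
      iqr_error = if (any(!is.na(.data$error))) {
        stats::IQR(.data$error, na.rm = TRUE)
      } else NA_real_,
      .groups = "drop")
  refs <- summ |>
    dplyr::filter(.data$train_norm == "none", .data$test_norm == "none") |>
    dplyr::select(dplyr::all_of(c("train_design", "test_design", "classifier",
                                  "validation")),
                  reference_error = "mean_error")
  summ |>
    dplyr::left_join(refs, by = c("train_design", "test_design",
                                  "classifier", "validation")) |>
    dplyr::mutate(delta_vs_none = .data$mean_error - .data$reference_error) |>
    dplyr::select(-"reference_error")
}

#' Plot an assessment grid
#'
#' Writes (a) a heatmap of mean misclassification over normalization pairs
#' x classifiers, faceted by design and validation target, and (b) per-cell
#' boxplots over repetitions.  Both plots are rendered from TSV files
#' written alongside them (`summary.tsv`, `results.tsv`), so the data
#' backing every figure is byte-stable and re-readable.
#'
#' @param result An `assessment_result`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
plot_results <- function(result, out_dir) {
  stopifnot(inherits(result, "data.frame"), nrow(result) > 0)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  summ <- summarize_results(result)
  paths <- c(summary = file.path(out_dir, "summary.tsv"),
             results = file.path(out_dir, "results.tsv"),
             heatmap = file.path(out_dir, "mean_error_heatmap.png"),
             boxplots = file.path(out_dir, "error_boxplots.png"))
  utils::write.table(summ, paths["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result, paths["results"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ_tab <- utils::read.table(paths["summary"], sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  res_tab <- utils::read.table(paths["results"], sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  summ_tab$norm_pair <- paste(summ_tab$train_norm, summ_tab$test_norm,
                              sep = " / ")
  res_tab$norm_pair <- paste(res_tab$train_norm, res_tab$test_norm,
                             sep = " / ")
  p1 <- ggplot2::ggplot(summ_tab,
                        ggplot2::aes(x = .data$classifier, y = .data$norm_pair,
                                     fill = .data$mean_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "mean error") +
    ggplot2::facet_grid(train_design ~ validation) +
    ggplot2::labs(x = "classifier", y = "train / test normalization",
                  title = "Mean misclassification proportion") +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(paths["heatmap"], p1, width = 9, height = 6, dpi = 120)
  p2 <- ggplot2::ggplot(res_tab[!is.na(res_tab$error), ],
                        ggplot2::aes(x = .data$classifier, y = .data$error,
                                     fill = .data$norm_pair)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::facet_grid(train_design ~ validation) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "classifier", y = "misclassification proportion",
                  fill = "train / test norm",
                  title = "Misclassification across repetitions") +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(paths["boxplots"], p2, width = 9, height = 6, dpi = 120)
  paths
}
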