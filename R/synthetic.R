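#' Specification for a synthetic paired study
#'
#' Declares the generator parameters for a paired microarray study with the
#' structure the benchmarking framework assumes: per-probe baselines, a
#' class effect on an informative probe subset, probe-replicate rows, and a
#' handling layer composed of a smooth monotone processing-order trend,
#' batch offsets, and noise.
#'
#' @param n_per_class Samples per class; `2 * n_per_class` must be
#'   divisible by 3 so the thirds array split is legal.
#' @param n_probes Number of distinct probes.
#' @param replicates_per_probe Replicate rows per probe.
#' @param n_informative Number of probes carrying the class effect.
#' @param class_effect_delta Class-mean difference on informative probes
#'   (log2 units).
#' @param bio_sd SD of the biological (and replicate) noise, log2 units.
#' @param trend_amplitude Range of the processing-order trend (log2 units
#'   from first to last array).
#' @param batch_offsets One additive offset per batch (arrays are cut into
#'   `length(batch_offsets)` contiguous processing-order batches).
#' @param handling_sd SD of the handling noise, log2 units.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = 24, n_probes = 120,
                         replicates_per_probe = 3, n_informative = 24,
                         class_effect_delta = 1.5, bio_sd = 0.5,
                         trend_amplitude = 1.0, batch_offsets = c(-0.5, 0.5),
                         handling_sd = 0.3, seed = 1L) {
  spec <- list(n_per_class = as.integer(n_per_class),
               n_probes = as.integer(n_probes),
               replicates_per_probe = as.integer(replicates_per_probe),
               n_informative = as.integer(n_informative),
               class_effect_delta = class_effect_delta, bio_sd = bio_sd,
               trend_amplitude = trend_amplitude,
               batch_offsets = batch_offsets, handling_sd = handling_sd,
               seed = as.integer(seed))
  if (spec$n_informative > spec$n_probes) {
    stop("n_informative cannot exceed n_probes")
  }
  if (spec$bio_sd < 0 || spec$handling_sd < 0) stop("SDs must be >= 0")
  if ((2L * spec$n_per_class) %% 3L != 0L) {
    stop("2 * n_per_class must be divisible by 3 (thirds split)")
  }
  if (spec$n_per_class < 1 || spec$n_probes < 1 ||
      spec$replicates_per_probe < 1) {
    stop("counts must be positive")
  }
  structure(spec, class = "fixture_spec")
}

#' Desk-scale default fixture
#'
#' The spec used throughout the test suite: 24 samples per class, 120
#' probes in triplicate (24 informative, class effect 1.5 log2 units,
#' biological SD 0.5), a one-unit processing-order trend, two batches at
#' -0.5/+0.5, handling SD 0.3, seed 1.  Its 48 samples split 32:16 under
#' the 2:1 rule and its 48 arrays split into thirds of 16.
#'
#' @return A `fixture_spec`.
#' @export
default_fixture <- function() fixture_spec()

# Smooth monotone trend over processing order: a logistic ramp rescaled to
# span exactly [0, trend_amplitude] from the first to the last array.
trend_profile <- function(n, amplitude) {
  raw <- stats::plogis(12 * ((seq_len(n) - 1) / (n - 1) - 0.5))
  amplitude * (raw - raw[1]) / (raw[n] - raw[1])
}

#' Generate a synthetic paired study
#'
#' Builds the two matrices of a [paired_study()] from additive log2-scale
#' layers and exponentiates them to the raw intensity scale, so the full
#' load -> log2 -> decomposition path is exercised:
#' * biological layer (per replicate row x sample): probe baseline
#'   (uniform on 6..10 log2 units) + `class_effect_delta` on informative
#'   probes for the second class + Gaussian noise `bio_sd`;
#' * handling layer (per row x array): monotone logistic processing-order
#'   ramp spanning `trend_amplitude` (with a per-row loading uniform on
#'   0.5..1.5) + contiguous batch offsets + Gaussian noise `handling_sd`.
#'
#' Uniform matrix = 2^(biological layer); non-uniform = 2^(biological +
#' handling), with sample `i` matched to array `i` (processing order =
#' collection order, classes in two contiguous runs, mirroring a study
#' arrayed in collection order).  The exact log2-scale layers are kept in
#' the `"ground_truth"` attribute for oracle tests; pipeline stages never
#' read them.
#'
#' @param spec A [fixture_spec()].
#' @return A raw-scale `paired_study` with attribute `ground_truth`
#'   (list of matrices `bio` and `handling`, log2 scale).
#' @export
generate_paired_study <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_samples <- 2L * spec$n_per_class
  n_rows <- spec$n_probes * spec$replicates_per_probe
  probe_names <- sprintf("p%04d", seq_len(spec$n_probes))
  row_probes <- rep(probe_names, each = spec$replicates_per_probe)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  array_ids <- sprintf("a%03d", seq_len(n_samples))
  classes <- rep(c("classA", "classB"), each = spec$n_per_class)
  informative <- probe_names[seq_len(spec$n_informative)]

  with_seed(spec$seed, {
    baseline <- stats::runif(spec$n_probes, 6, 10)
    bio <- matrix(rep(baseline, each = spec$replicates_per_probe),
                  nrow = n_rows, ncol = n_samples) +
      matrix(stats::rnorm(n_rows * n_samples, sd = spec$bio_sd),
             nrow = n_rows)
    bio[row_probes %in% informative, classes == "classB"] <-
      bio[row_probes %in% informative, classes == "classB"] +
      spec$class_effect_delta

    n_batches <- length(spec$batch_offsets)
    batch_of <- rep(seq_len(n_batches), each = ceiling(n_samples / n_batches),
                    length.out = n_samples)
    loading <- stats::runif(n_rows, 0.5, 1.5)
    trend <- trend_profile(n_samples, spec$trend_amplitude)
    handling <- outer(loading, trend) +
      matrix(rep(spec$batch_offsets[batch_of], each = n_rows),
             nrow = n_rows) +
      matrix(stats::rnorm(n_rows * n_samples, sd = spec$handling_sd),
             nrow = n_rows)

    dimnames(bio) <- list(row_probes, sample_ids)
    handling_named <- handling
    dimnames(handling_named) <- list(row_probes, array_ids)

    study <- paired_study(
      uniform = expression_matrix(2^bio, probe_ids = row_probes,
                                  array_ids = sample_ids, scale = "raw"),
      nonuniform = expression_matrix(2^(bio + handling),
                                     probe_ids = row_probes,
                                     array_ids = array_ids, scale = "raw"),
      samples = sample_annotation(sample_ids, classes),
      arrays = array_annotation(array_ids, seq_len(n_samples),
                                paste0("batch", batch_of)),
      sample_to_array = stats::setNames(array_ids, sample_ids))
    attr(study, "ground_truth") <- list(bio = bio, handling = handling_named)
    study
  })
}

#' Write a generated study as four TSV files
#'
#' `uniform.tsv`, `nonuniform.tsv` (raw expression matrices),
#' `samples.tsv`, `arrays.tsv` (annotations), in the formats the loaders
#' expect; a synthetic ground-truth archive
#' (`ground_truth_synthetic.tsv`) is added when the study carries one.
#'
#' @param study A `paired_study`, e.g. from [generate_paired_study()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
write_fixture_files <- function(study, dir) {
  stopifnot(inherits(study, "paired_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(uniform = file.path(dir, "uniform.tsv"),
             nonuniform = file.path(dir, "nonuniform.tsv"),
             samples = file.path(dir, "samples.tsv"),
             arrays = file.path(dir, "arrays.tsv"))
  write_expression_matrix(study$uniform, paths["uniform"])
  write_expression_matrix(study$nonuniform, paths["nonuniform"])
  utils::write.table(study$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$arrays, paths["arrays"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- attr(study, "ground_truth")
  if (!is.null(gt)) {
    gt_path <- file.path(dir, "ground_truth_synthetic.tsv")
    # long format: layer, probe row index, column id, value
    long <- rbind(
      data.frame(layer = "bio", row = seq_len(nrow(gt$bio)),
                 probe_id = rownames(gt$bio),
                 column = rep(colnames(gt$bio), each = nrow(gt$bio)),
                 value = as.vector(gt$bio), stringsAsFactors = FALSE),
      data.frame(layer = "handling", row = seq_len(nrow(gt$handling)),
                 probe_id = rownames(gt$handling),
                 column = rep(colnames(gt$handling),
                              each = nrow(gt$handling)),
                 value = as.vector(gt$handling), stringsAsFactors = FALSE))
    utils::write.table(long, gt_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, ground_truth = gt_path)
  }
  paths
}

#' Load a paired study from fixture files
#'
#' Reads the four TSVs written by [write_fixture_files()] back into a
#' validated raw-scale [paired_study()].
#'
#' @param dir Directory containing `uniform.tsv`, `nonuniform.tsv`,
#'   `samples.tsv`, `arrays.tsv`.
#' @return A `paired_study`.
#' @export
load_paired_study <- function(dir) {
  paired_study(
    uniform = load_expression_matrix(file.path(dir, "uniform.tsv")),
    nonuniform = load_expression_matrix(file.path(dir, "nonuniform.tsv")),
    samples = load_sample_annotation(file.path(dir, "samples.tsv")),
    arrays = load_array_annotation(file.path(dir, "arrays.tsv")))
}
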