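#' Registries of normalization strategies
#'
#' `train_normalizations()` lists the three named training-data
#' normalization methods (median, quantile, variance-stabilizing); `"none"`
#' is additionally accepted everywhere as the no-normalization reference.
#' `test_normalizations()` lists the seven named test-data strategies: each
#' training method applied to the test set alone or frozen toward the
#' training reference, plus pooled quantile normalization; again `"none"`
#' is the reference outside the seven.
#'
#' @return Character vector of registry names.
#' @export
train_normalizations <- function() c("median", "quantile", "vsn")

#' @rdname train_normalizations
#' @export
test_normalizations <- function() {
  c("median_alone", "quantile_alone", "vsn_alone",
    "median_frozen", "quantile_frozen", "vsn_frozen",
    "pooled_quantile")
}

# Map values of one array onto a frozen sorted reference vector.  Ties share
# the mean of the reference values at their tied ranks, so tied inputs stay
# tied and the map is monotone nondecreasing.
quantile_map <- function(v, ref) {
  if (length(v) != length(ref)) {
    stop("array length (", length(v), ") does not match reference length (",
         length(ref), ")")
  }
  r_lo <- rank(v, ties.method = "min")
  r_hi <- rank(v, ties.method = "max")
  out <- ref[r_lo]                      # bit-exact for untied values
  tied <- r_hi > r_lo
  if (any(tied)) {
    cs <- cumsum(c(0, ref))
    out[tied] <- (cs[r_hi[tied] + 1] - cs[r_lo[tied]]) /
      (r_hi[tied] - r_lo[tied] + 1)
  }
  out
}

# Mean of order statistics across arrays: the frozen quantile reference.
mean_order_statistics <- function(values) {
  unname(rowMeans(apply(values, 2, sort)))
}

quantile_normalize_matrix <- function(values, ref = NULL) {
  if (is.null(ref)) ref <- mean_order_statistics(values)
  out <- apply(values, 2, quantile_map, ref = ref)
  dimnames(out) <- dimnames(values)
  list(values = out, ref = ref)
}

# ---- simplified variance-stabilizing transform ------------------------------
#
# Per-array affine calibration against the across-array mean order
# statistics of the raw intensities, followed by a shared inverse
# hyperbolic sine with glog scale s0 chosen to flatten the per-probe spread
# across intensity strata.  Output is divided by log(2) so high intensities
# sit on a log2-like scale.

vsn_calibrate <- function(raw_col, calib_quantiles) {
  fit <- stats::lm.fit(cbind(1, calib_quantiles), sort(raw_col))
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  if (!is.finite(b) || b <= 0) {
    stop("degenerate array: nonpositive calibration slope")
  }
  (raw_col - a) / b
}

vsn_fit <- function(raw, n_strata = 5) {
  calib_q <- mean_order_statistics(raw)
  cal <- apply(raw, 2, vsn_calibrate, calib_quantiles = calib_q)
  m <- stats::median(abs(cal))
  if (m <= 0) m <- 1
  crit <- function(log_s0) {
    y <- asinh(cal / exp(log_s0))
    sds <- apply(y, 1, stats::sd)
    strata <- cut(rank(rowMeans(y), ties.method = "first"),
                  breaks = n_strata, labels = FALSE)
    stats::var(tapply(sds, strata, mean))
  }
  opt <- stats::optimize(crit, interval = log(m) + c(-7, 7))
  s0 <- exp(opt$minimum)
  y <- asinh(cal / s0) / log(2)
  dimnames(y) <- dimnames(raw)
  list(values = y, calib_quantiles = calib_q, s0 = s0,
       target_quantiles = mean_order_statistics(y))
}

vsn_apply_frozen <- function(raw_col, params) {
  cal <- vsn_calibrate(raw_col, params$calib_quantiles)
  y <- asinh(cal / params$s0) / log(2)
  quantile_map(y, params$target_quantiles)
}

as_raw_values <- function(x) {
  if (x$scale == "raw") x$values else 2^x$values
}

# -----------------------------------------------------------------------------

#' Normalize training data and freeze the reference
#'
#' Applies one of the training normalization methods and stores the frozen
#' reference that the matching test-data strategies reuse:
#' \describe{
#'   \item{none}{identity; empty reference.}
#'   \item{median}{each array is shifted so its median equals the median of
#'     the per-array medians, which is stored as `reference_median`.}
#'   \item{quantile}{each array's sorted values are replaced by the
#'     across-array mean of order statistics, stored as
#'     `reference_quantiles`.  Ties share the mean of the reference values
#'     at their tied ranks.}
#'   \item{vsn}{simplified variance-stabilizing normalization: per-array
#'     affine calibration inside an inverse hyperbolic sine whose glog
#'     scale is fitted to flatten the per-probe spread across intensity
#'     strata; fitted parameters and pooled target quantiles are stored.}
#' }
#'
#' @param x An [expression_matrix()]; log2 scale for median/quantile, raw or
#'   log2 for vsn (which includes its own transform).
#' @param method One of `"none"`, `"median"`, `"quantile"`, `"vsn"`.
#' @return List with elements `normalized` (an `expression_matrix`, log2
#'   scale) and `reference` (a `normalization_reference`).
#' @export
normalize_train <- function(x, method = c("none", "median", "quantile", "vsn")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expression_matrix"))
  if (method %in% c("median", "quantile") && x$scale != "log2") {
    stop(method, " normalization expects log2-scale data")
  }
  if (method %in% c("quantile", "vsn") && ncol(x$values) < 2) {
    stop(method, " normalization needs at least 2 arrays")
  }
  ref <- structure(list(method = method), class = "normalization_reference")
  out <- switch(method,
    none = x$values,
    median = {
      med <- apply(x$values, 2, stats::median)
      ref$reference_median <- stats::median(med)
      sweep(x$values, 2, med - ref$reference_median)
    },
    quantile = {
      qn <- quantile_normalize_matrix(x$values)
      ref$reference_quantiles <- qn$ref
      qn$values
    },
    vsn = {
      fit <- vsn_fit(as_raw_values(x))
      ref$vsn_params <- fit[c("calib_quantiles", "s0", "target_quantiles")]
      fit$values
    })
  list(normalized = expression_matrix(out, probe_ids = probe_ids(x),
                                      array_ids = array_ids(x),
                                      scale = "log2"),
       reference = ref)
}

#' @export
print.normalization_reference <- function(x, ...) {
  cat(sprintf("normalization_reference: method=%s\n", x$method))
  invisible(x)
}

#' Normalize test data under one of the seven strategies
#'
#' The `*_alone` strategies normalize the test set in isolation (exactly
#' [normalize_train()] on the test arrays).  The `*_frozen` strategies map
#' each test array, one at a time, onto the reference frozen from the
#' training data — they never read other test arrays, so normalizing
#' arrays jointly or singly gives identical results.  `pooled_quantile`
#' quantile-normalizes the concatenation of training and test arrays and
#' returns the test columns.  `"none"` is the identity reference.
#'
#' @param x_test Test-set [expression_matrix()] (log2 scale except for the
#'   vsn strategies, which accept raw).
#' @param strategy One of `"none"`, [test_normalizations()].
#' @param reference A `normalization_reference` from [normalize_train()];
#'   required by the frozen strategies and checked for a matching method.
#' @param x_train The training [expression_matrix()] (pre-normalization);
#'   required by `pooled_quantile`.
#' @return The normalized test `expression_matrix` (log2 scale).
#' @export
normalize_test <- function(x_test,
                           strategy = c("none", "median_alone",
                                        "quantile_alone", "vsn_alone",
                                        "median_frozen", "quantile_frozen",
                                        "vsn_frozen", "pooled_quantile"),
                           reference = NULL, x_train = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x_test, "expression_matrix"))
  frozen_method <- c(median_frozen = "median", quantile_frozen = "quantile",
                     vsn_frozen = "vsn")
  if (strategy %in% names(frozen_method)) {
    if (is.null(reference) || !inherits(reference, "normalization_reference")) {
      stop("frozen strategies require a normalization_reference")
    }
    if (reference$method != frozen_method[[strategy]]) {
      stop("reference method '", reference$method,
           "' does not match strategy '", strategy, "'")
    }
  }
  if (strategy %in% c("none", "median_frozen", "quantile_frozen",
                      "pooled_quantile") && x_test$scale != "log2") {
    stop(strategy, " expects log2-scale test data")
  }
  out <- switch(strategy,
    none = x_test$values,
    median_alone = normalize_train(x_test, "median")$normalized$values,
    quantile_alone = normalize_train(x_test, "quantile")$normalized$values,
    vsn_alone = normalize_train(x_test, "vsn")$normalized$values,
    median_frozen = {
      med <- apply(x_test$values, 2, stats::median)
      sweep(x_test$values, 2, med - reference$reference_median)
    },
    quantile_frozen = {
      v <- apply(x_test$values, 2, quantile_map,
                 ref = reference$reference_quantiles)
      dimnames(v) <- dimnames(x_test$values)
      v
    },
    vsn_frozen = {
      v <- apply(as_raw_values(x_test), 2, vsn_apply_frozen,
                 params = reference$vsn_params)
      dimnames(v) <- dimnames(x_test$values)
      v
    },
    pooled_quantile = {
      if (is.null(x_train) || !inherits(x_train, "expression_matrix")) {
        stop("pooled_quantile requires the training expression matrix")
      }
      if (x_train$scale != "log2") stop("pooled_quantile expects log2-scale training data")
      if (nrow(x_train$values) != nrow(x_test$values)) {
        stop("training and test matrices must share the probe set")
      }
      pooled <- cbind(x_train$values, x_test$values)
      qn <- quantile_normalize_matrix(pooled)
      qn$values[, ncol(x_train$values) + seq_len(ncol(x_test$values)),
                drop = FALSE]
    })
  expression_matrix(out, probe_ids = probe_ids(x_test),
                    array_ids = array_ids(x_test), scale = "log2")
}

#' Location-only batch correction
#'
#' Per probe and per batch, subtracts the batch mean and adds back the
#' grand mean, equalizing batch means probe-by-probe while leaving
#' within-batch structure untouched.  Off by default in the pipeline.
#'
#' @param x A log2-scale [expression_matrix()].
#' @param batches Batch label per array (named by, or ordered as, the array
#'   IDs); every batch needs at least 2 arrays.
#' @return The corrected `expression_matrix`.
#' @export
batch_correct <- function(x, batches) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale != "log2") stop("batch correction expects log2-scale data")
  if (is.null(names(batches))) names(batches) <- array_ids(x)
  batches <- as.character(batches[array_ids(x)])
  if (anyNA(batches)) stop("every array needs a batch label")
  tab <- table(batches)
  if (any(tab < 2)) {
    stop("singleton batch(es): ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  v <- x$values
  grand <- rowMeans(v)
  for (b in unique(batches)) {
    cols <- which(batches == b)
    v[, cols] <- v[, cols, drop = FALSE] -
      rowMeans(v[, cols, drop = FALSE]) + grand
  }
  expression_matrix(v, scale = "log2")
}

#' Serialize a normalization reference
#'
#' Key-value text file holding the method name, scalar parameters and any
#' quantile vectors, sufficient to re-freeze test normalization in a later
#' session.
#'
#' @param reference A `normalization_reference`.
#' @param path Output path.
#' @return `path` invisibly (write) or the reference (read).
#' @export
write_normalization_reference <- function(reference, path) {
  num <- function(v) paste(format(v, digits = 17), collapse = ",")
  lines <- c(paste0("method=", reference$method))
  if (!is.null(reference$reference_median)) {
    lines <- c(lines, paste0("reference_median=", num(reference$reference_median)))
  }
  if (!is.null(reference$reference_quantiles)) {
    lines <- c(lines, paste0("reference_quantiles=",
                             num(reference$reference_quantiles)))
  }
  if (!is.null(reference$vsn_params)) {
    lines <- c(lines,
               paste0("vsn_s0=", num(reference$vsn_params$s0)),
               paste0("vsn_calib_quantiles=",
                      num(reference$vsn_params$calib_quantiles)),
               paste0("vsn_target_quantiles=",
                      num(reference$vsn_params$target_quantiles)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_normalization_reference
#' @export
load_normalization_reference <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  nums <- function(key) as.numeric(strsplit(vals[[key]], ",", fixed = TRUE)[[1]])
  ref <- structure(list(method = vals$method),
                   class = "normalization_reference")
  if (!is.null(vals$reference_median)) ref$reference_median <- nums("reference_median")
  if (!is.null(vals$reference_quantiles)) {
    ref$reference_quantiles <- nums("reference_quantiles")
  }
  if (!is.null(vals$vsn_s0)) {
    ref$vsn_params <- list(calib_quantiles = nums("vsn_calib_quantiles"),
                           s0 = nums("vsn_s0"),
                           target_quantiles = nums("vsn_target_quantiles"))
  }
  ref
}
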