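two_arrays <- function() {
  tiny_em(c(1, 2, 3, 4, 5, 6), c("p1", "p2", "p3"), c("a1", "a2"))
}

test_that("training quantile normalization equals the mean of order statistics", {
  qn <- normalize_train(two_arrays(), "quantile")
  expect_identical(unname(qn$normalized$values[, "a1"]), c(2.5, 3.5, 4.5))
  expect_identical(unname(qn$normalized$values[, "a2"]), c(2.5, 3.5, 4.5))
  expect_identical(qn$reference$reference_quantiles, c(2.5, 3.5, 4.5))

  # after normalization all arrays share one sorted vector (fixture-wide)
  sim <- expression_matrix(fix_bio$values[, 1:10] + fix_hnd$values[, 1:10],
                           scale = "log2")
  nq <- normalize_train(sim, "quantile")$normalized
  sorted <- apply(nq$values, 2, sort)
  expect_equal(sorted, matrix(sorted[, 1], nrow(sorted), ncol(sorted),
                              dimnames = dimnames(sorted)),
               tolerance = 1e-12)
})

test_that("quantile normalization agrees with limma on untied data", {
  set.seed(10)
  v <- matrix(rnorm(200), 40, 5,
              dimnames = list(sprintf("p%d", 1:40), sprintf("a%d", 1:5)))
  ours <- normalize_train(expression_matrix(v, scale = "log2"),
                          "quantile")$normalized$values
  theirs <- limma::normalizeQuantiles(v)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("median normalization targets the median of per-array medians", {
  x <- tiny_em(c(1, 2, 3, 3, 4, 5), c("p1", "p2", "p3"), c("a1", "a2"))
  mn <- normalize_train(x, "median")
  expect_identical(mn$reference$reference_median, 3)
  expect_identical(unname(apply(mn$normalized$values, 2, median)), c(3, 3))
  # rank order within each array is preserved exactly
  expect_identical(apply(mn$normalized$values, 2, rank),
                   apply(x$values, 2, rank))
})

test_that("method 'none' is the identity and errors are raised early", {
  x <- two_arrays()
  expect_identical(normalize_train(x, "none")$normalized$values, x$values)
  one <- tiny_em(1:3, c("p1", "p2", "p3"), "a1")
  expect_error(normalize_train(one, "quantile"), "at least 2 arrays")
  raw <- tiny_em(1:6, c("p1", "p2", "p3"), c("a1", "a2"), scale = "raw")
  expect_error(normalize_train(raw, "median"), "log2")
})

test_that("frozen strategies map each test array onto the stored reference", {
  train <- expression_matrix(fix_bio$values[, 1:20], scale = "log2")
  test <- expression_matrix(fix_bio$values[, 21:30], scale = "log2")

  qt <- normalize_train(train, "quantile")
  fq <- normalize_test(test, "quantile_frozen", reference = qt$reference)
  for (j in seq_len(ncol(fq$values))) {
    expect_identical(unname(sort(fq$values[, j])),
                     qt$reference$reference_quantiles)
  }

  md <- normalize_train(train, "median")
  x7 <- tiny_em(c(5, 7, 30), c("p1", "p2", "p3"), "t1")
  ref3 <- structure(list(method = "median", reference_median = 3),
                    class = "normalization_reference")
  fm <- normalize_test(x7, "median_frozen", reference = ref3)
  expect_identical(unname(fm$values[, 1]), c(5, 7, 30) - 4)  # shift = 7 - 3

  # frozen strategies never read other test arrays: single vs joint identical
  joint <- normalize_test(test, "quantile_frozen", reference = qt$reference)
  for (j in 1:3) {
    solo <- normalize_test(
      expression_matrix(test$values[, j, drop = FALSE], scale = "log2"),
      "quantile_frozen", reference = qt$reference)
    expect_identical(solo$values[, 1], joint$values[, j])
  }
  expect_error(normalize_test(test, "quantile_frozen",
                              reference = md$reference), "does not match")
  expect_error(normalize_test(test, "median_frozen"), "reference")
})

test_that("tied test values share the mean of reference values at tied ranks", {
  ref <- structure(list(method = "quantile",
                        reference_quantiles = c(10, 20, 30, 40)),
                   class = "normalization_reference")
  x <- tiny_em(c(2, 1, 1, 3), sprintf("p%d", 1:4), "a1")
  fq <- normalize_test(x, "quantile_frozen", reference = ref)
  # values 1,1 occupy ranks 1-2 -> (10+20)/2; 2 -> 30; 3 -> 40
  expect_identical(unname(fq$values[, 1]), c(30, 15, 15, 40))
})

test_that("pooled quantile normalization concatenates train and test", {
  train <- tiny_em(1:3, c("p1", "p2", "p3"), "tr1")
  test <- tiny_em(4:6, c("p1", "p2", "p3"), "te1")
  pq <- normalize_test(test, "pooled_quantile", x_train = train)
  expect_identical(unname(pq$values[, 1]), c(2.5, 3.5, 4.5))
  expect_error(normalize_test(test, "pooled_quantile"), "training")

  # the *_alone strategies equal normalize_train on the test set alone
  test10 <- expression_matrix(fix_bio$values[, 1:10], scale = "log2")
  expect_identical(normalize_test(test10, "quantile_alone")$values,
                   normalize_train(test10, "quantile")$normalized$values)
  expect_identical(normalize_test(test10, "median_alone")$values,
                   normalize_train(test10, "median")$normalized$values)
})

test_that("simplified VSN is monotone per array and flattens the variance trend", {
  sim <- expression_matrix(fix_bio$values[, 1:24] + fix_hnd$values[, 1:24],
                           scale = "log2")
  nv <- normalize_train(sim, "vsn")
  for (j in c(1, 12, 24)) {
    o <- order(sim$values[, j])
    expect_false(is.unsorted(nv$normalized$values[o, j]))
  }
  # variance stabilization: on the raw fluorescence scale the per-probe
  # spread grows with intensity; after the transform the per-stratum mean
  # spreads are nearly constant
  stratum_spread <- function(v) {
    sds <- apply(v, 1, sd)
    st <- cut(rank(rowMeans(v), ties.method = "first"), 5, labels = FALSE)
    means <- tapply(sds, st, mean)
    diff(range(means)) / mean(means)
  }
  expect_lt(stratum_spread(nv$normalized$values), stratum_spread(2^sim$values))

  # frozen vsn maps each test array onto the stored target quantiles
  test <- expression_matrix(fix_bio$values[, 25:30], scale = "log2")
  fv <- normalize_test(test, "vsn_frozen", reference = nv$reference)
  for (j in seq_len(ncol(fv$values))) {
    expect_equal(unname(sort(fv$values[, j])),
                 nv$reference$vsn_params$target_quantiles, tolerance = 1e-12)
  }
})

test_that("batch correction equalizes per-probe batch means and nothing more", {
  x <- expression_matrix(fix_bio$values[, 1:12], scale = "log2")
  single <- batch_correct(x, rep("b1", 12))
  expect_equal(single$values, x$values, tolerance = 1e-12)

  batches <- rep(c("b1", "b2"), each = 6)
  shifted <- x
  shifted$values[, 7:12] <- shifted$values[, 7:12] + 2
  bc <- batch_correct(shifted, batches)
  m1 <- rowMeans(bc$values[, 1:6]); m2 <- rowMeans(bc$values[, 7:12])
  expect_equal(m1, m2, tolerance = 1e-12)
  # brute-force group-mean oracle: every batch mean equals the grand mean
  grand <- rowMeans(shifted$values)
  expect_equal(rowMeans(bc$values[, 1:6]), grand, tolerance = 1e-12)
  # within-batch deviations untouched
  expect_equal(sweep(bc$values[, 1:6], 1, m1),
               sweep(shifted$values[, 1:6], 1, rowMeans(shifted$values[, 1:6])),
               tolerance = 1e-12)
  expect_error(batch_correct(x, c(rep("b1", 11), "b2")), "singleton")
})

test_that("registries count three training and seven test strategies", {
  expect_length(train_normalizations(), 3)
  expect_length(test_normalizations(), 7)
  expect_false("none" %in% c(train_normalizations(), test_normalizations()))
})

test_that("normalization references serialize and reload", {
  train <- expression_matrix(fix_bio$values[, 1:10], scale = "log2")
  for (m in c("median", "quantile", "vsn")) {
    ref <- normalize_train(train, m)$reference
    f <- withr::local_tempfile(fileext = ".txt")
    write_normalization_reference(ref, f)
    back <- load_normalization_reference(f)
    expect_identical(back$method, m)
    test <- expression_matrix(fix_bio$values[, 11:13], scale = "log2")
    strat <- paste0(m, "_frozen")
    expect_equal(normalize_test(test, strat, reference = back)$values,
                 normalize_test(test, strat, reference = ref)$values,
                 tolerance = 1e-12)
  }
})
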