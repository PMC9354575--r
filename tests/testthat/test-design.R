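# Minimal paired effects for design tests: 6 samples (3 per class) and 6
# arrays whose IDs are deliberately shuffled relative to processing order.
toy_effects <- function() {
  probes <- c("p1", "p2")
  bio <- biological_effects(
    matrix(as.numeric(1:12), nrow = 2,
           dimnames = list(probes, sprintf("s%d", 1:6))),
    class_labels = c(A = "A", "A", "A", "B", "B", "B") |>
      stats::setNames(sprintf("s%d", 1:6)))
  hnd <- handling_effects(
    matrix(0, nrow = 2, ncol = 6,
           dimnames = list(probes, c("a6", "a5", "a4", "a3", "a2", "a1"))),
    processing_order = stats::setNames(6:1, c("a6", "a5", "a4", "a3", "a2", "a1")),
    batch = stats::setNames(rep("b1", 6), c("a6", "a5", "a4", "a3", "a2", "a1")))
  list(bio = bio, hnd = hnd)
}

test_that("split_study takes middle-third arrays for test and stratifies samples 2:1", {
  toy <- toy_effects()
  sp <- split_study(toy$bio, toy$hnd, seed = 1)
  # processing orders 3 and 4 are the middle third, regardless of ID order
  expect_setequal(sp$test_array_ids, c("a4", "a3"))
  expect_setequal(sp$train_array_ids, c("a1", "a2", "a5", "a6"))
  expect_identical(length(sp$train_sample_ids), 4L)
  expect_identical(length(sp$test_sample_ids), 2L)

  # class-stratified 2:1 on the default fixture, for several seeds
  for (seed in 1:5) {
    sp <- split_study(fix_bio, fix_hnd, seed = seed)
    tr <- table(fix_bio$class_labels[sp$train_sample_ids])
    te <- table(fix_bio$class_labels[sp$test_sample_ids])
    expect_identical(unname(as.integer(tr)), c(16L, 16L))
    expect_identical(unname(as.integer(te)), c(8L, 8L))
    expect_length(intersect(sp$train_sample_ids, sp$test_sample_ids), 0)
    expect_setequal(c(sp$train_array_ids, sp$test_array_ids),
                    colnames(fix_hnd$values))
  }
})

test_that("split_study rejects counts not divisible into thirds", {
  bad_bio <- biological_effects(
    matrix(1:8, nrow = 2, dimnames = list(c("p1", "p2"), sprintf("s%d", 1:4))),
    class_labels = rep(c("A", "B"), each = 2))
  bad_hnd <- handling_effects(
    matrix(0, 2, 4, dimnames = list(c("p1", "p2"), sprintf("a%d", 1:4))),
    processing_order = 1:4, batch = rep("b", 4))
  expect_error(split_study(bad_bio, bad_hnd, 1), "divisible by 3")
})

test_that("confounding design aligns class with processing order", {
  asg <- assign_arrays(sprintf("s%d", 1:4), c("A", "A", "B", "B"),
                       sprintf("a%d", 1:4), 1:4, design = "confounding",
                       seed = 9)
  # class A (first in sort order) receives the earliest arrays
  got_a <- asg$sample_id[asg$array_id %in% c("a1", "a2")]
  expect_setequal(got_a, c("s1", "s2"))
  # rank-sum of class-A processing orders is the minimum possible
  for (seed in 1:10) {
    sp <- split_study(fix_bio, fix_hnd, seed = seed)
    cls <- fix_bio$class_labels[sp$train_sample_ids]
    ord <- fix_hnd$processing_order[sp$train_array_ids]
    asg <- assign_arrays(sp$train_sample_ids, cls, sp$train_array_ids, ord,
                         design = "confounding", seed = seed)
    expect_equal(sum(rank(fix_hnd$processing_order[asg$array_id])[
      fix_bio$class_labels[asg$sample_id] == "classA"]),
      sum(seq_len(sum(cls == "classA"))))
  }
})

test_that("balanced design places equal class counts in every block", {
  cls4 <- stats::setNames(c("A", "A", "B", "B"), sprintf("s%d", 1:4))
  for (seed in 1:10) {
    asg <- assign_arrays(names(cls4), cls4, sprintf("a%d", 1:4), 1:4,
                         design = "balanced", seed = seed, block_size = 2)
    blocks <- split(cls4[asg$sample_id], rep(1:2, each = 2))
    for (b in blocks) expect_setequal(unname(b), c("A", "B"))
  }
  # block class proportions equal global proportions on the fixture
  sp <- split_study(fix_bio, fix_hnd, seed = 2)
  cls <- fix_bio$class_labels[sp$train_sample_ids]
  ord <- fix_hnd$processing_order[sp$train_array_ids]
  asg <- assign_arrays(sp$train_sample_ids, cls, sp$train_array_ids, ord,
                       design = "balanced", seed = 3, block_size = 4)
  by_block <- split(fix_bio$class_labels[asg$sample_id],
                    rep(seq_len(8), each = 4))
  for (b in by_block) {
    expect_identical(unname(as.integer(table(b))), c(2L, 2L))
  }
  expect_error(assign_arrays(sprintf("s%d", 1:4), c("A", "A", "A", "B"),
                             sprintf("a%d", 1:4), 1:4, design = "balanced",
                             seed = 1, block_size = 2),
               "equal class counts")
  expect_error(assign_arrays(sprintf("s%d", 1:4), c("A", "A", "B", "B"),
                             sprintf("a%d", 1:4), 1:4, design = "balanced",
                             seed = 1, block_size = 3), "even")
})

test_that("every design and seed yields a bijection within the part", {
  sp <- split_study(fix_bio, fix_hnd, seed = 5)
  cls <- fix_bio$class_labels[sp$train_sample_ids]
  ord <- fix_hnd$processing_order[sp$train_array_ids]
  for (design in c("confounding", "balanced", "complete_random")) {
    for (seed in c(1, 99)) {
      asg <- assign_arrays(sp$train_sample_ids, cls, sp$train_array_ids, ord,
                           design = design, seed = seed)
      expect_setequal(asg$array_id, sp$train_array_ids)
      expect_setequal(asg$sample_id, sp$train_sample_ids)
      expect_false(anyDuplicated(asg$sample_id) > 0)
      expect_false(anyDuplicated(asg$array_id) > 0)
    }
  }
  expect_error(assign_arrays(sprintf("s%d", 1:3), c("A", "A", "B"),
                             sprintf("a%d", 1:2), 1:2, design = "confounding"),
               "as many arrays as samples")
})

test_that("design assignments serialize to TSV and back", {
  asg <- assign_arrays(sprintf("s%d", 1:4), c("A", "A", "B", "B"),
                       sprintf("a%d", 1:4), 1:4, design = "balanced",
                       seed = 7, block_size = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_design_assignment(asg, f)
  back <- load_design_assignment(f)
  expect_identical(back$array_id, asg$array_id)
  expect_identical(back$sample_id, asg$sample_id)
  expect_identical(attr(back, "design_name"), "balanced")
  expect_identical(attr(back, "seed"), 7L)
})

test_that("rehybridize sums biological and assigned handling columns", {
  toy <- toy_effects()
  asg <- assign_arrays(sprintf("s%d", 1:6), toy$bio$class_labels,
                       colnames(toy$hnd$values), toy$hnd$processing_order,
                       design = "complete_random", seed = 2)
  # zero handling: output equals bio restricted to the assigned samples
  out <- rehybridize(toy$bio, toy$hnd, asg)
  expect_identical(out$values, toy$bio$values)
  expect_identical(out$scale, "log2")

  # elementwise-sum toy: bio [1,2] + handling [0.5,-0.5] = [1.5, 1.5]
  b1 <- biological_effects(matrix(c(1, 2), 2, dimnames = list(c("p1", "p2"), "s1")),
                           class_labels = "A")
  h1 <- handling_effects(matrix(c(0.5, -0.5), 2,
                                dimnames = list(c("p1", "p2"), "a1")),
                         processing_order = 1L, batch = "b")
  a1 <- structure(data.frame(array_id = "a1", sample_id = "s1"),
                  design_name = "confounding", seed = 1L,
                  class = c("design_assignment", "data.frame"))
  expect_identical(unname(rehybridize(b1, h1, a1)$values[, 1]), c(1.5, 1.5))

  # full-fixture brute-force re-summation oracle
  sp <- split_study(fix_bio, fix_hnd, seed = 4)
  cls <- fix_bio$class_labels[sp$train_sample_ids]
  ord <- fix_hnd$processing_order[sp$train_array_ids]
  asg <- assign_arrays(sp$train_sample_ids, cls, sp$train_array_ids, ord,
                       design = "balanced", seed = 6)
  sim <- rehybridize(fix_bio, fix_hnd, asg)
  for (i in seq_len(nrow(asg))) {
    expect_identical(sim$values[, asg$sample_id[i]],
                     fix_bio$values[, asg$sample_id[i]] +
                       fix_hnd$values[, asg$array_id[i]])
  }
  # rehybridize output minus bio reproduces exactly the assigned handling
  got <- sim$values - fix_bio$values[, colnames(sim$values)]
  arr_of <- stats::setNames(asg$array_id, asg$sample_id)
  expect_equal(unname(got),
               unname(fix_hnd$values[, arr_of[colnames(sim$values)]]),
               tolerance = 1e-12)
})

test_that("rehybridize validates probes and assignment coverage", {
  toy <- toy_effects()
  bad_h <- toy$hnd
  rownames(bad_h$values) <- c("p1", "pX")
  asg <- assign_arrays(sprintf("s%d", 1:6), toy$bio$class_labels,
                       colnames(toy$hnd$values), toy$hnd$processing_order,
                       design = "complete_random", seed = 2)
  expect_error(rehybridize(toy$bio, bad_h, asg), "probe IDs")
  bad_asg <- asg
  bad_asg$sample_id[1] <- "s99"
  expect_error(rehybridize(toy$bio, toy$hnd, bad_asg), "s99")
})

test_that("make_benchmark is the handling-free test set", {
  sp <- split_study(fix_bio, fix_hnd, seed = 8)
  bench <- make_benchmark(fix_bio, sp)
  expect_identical(ncol(bench$values), length(sp$test_sample_ids))
  expect_setequal(array_ids(bench), sp$test_sample_ids)
  # definitional equivalence with rehybridization under zero handling
  zero <- amplify_handling_effects(fix_hnd, 0)
  cls <- fix_bio$class_labels[sp$test_sample_ids]
  ord <- fix_hnd$processing_order[sp$test_array_ids]
  asg <- assign_arrays(sp$test_sample_ids, cls, sp$test_array_ids, ord,
                       design = "complete_random", seed = 1)
  expect_identical(rehybridize(fix_bio, zero, asg)$values, bench$values)
})
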