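# Shared fixtures, built once per test run.  The default desk-scale study
# (48 samples, 120 probes in triplicate) backs most module tests; its
# ground-truth layers live in the "ground_truth" attribute.

fix_study <- generate_paired_study(default_fixture())
fix_log2 <- study_log2(fix_study)
fix_bio <- estimate_biological_effects(fix_log2)
fix_hnd <- estimate_handling_effects(fix_log2)
fix_truth <- attr(fix_study, "ground_truth")

# Small hand-built expression matrix on a chosen scale.
tiny_em <- function(values, probe_ids, array_ids, scale = "log2") {
  expression_matrix(matrix(values, nrow = length(probe_ids),
                           dimnames = list(NULL, NULL)),
                    probe_ids = probe_ids, array_ids = array_ids,
                    scale = scale)
}

# Independent standardized nearest-centroid oracle: plain loops over the
# textbook formula, sharing no code with the package implementation.
nearest_centroid_oracle <- function(x, y, newx) {
  labels <- sort(unique(y))
  n <- ncol(x); k <- length(labels)
  cent <- sapply(labels, function(cl) apply(x[, y == cl, drop = FALSE], 1, mean))
  pooled <- numeric(nrow(x))
  for (cl in labels) {
    for (j in which(y == cl)) pooled <- pooled + (x[, j] - cent[, cl])^2
  }
  s <- sqrt(pooled / (n - k))
  s0 <- median(s)
  prior <- as.numeric(table(factor(y, levels = labels))) / n
  apply(newx, 2, function(v) {
    scores <- vapply(seq_along(labels), function(i) {
      sum((v - cent[, i])^2 / (s + s0)^2) - 2 * log(prior[i])
    }, 0)
    labels[which.min(scores)]
  })
}

# Well-separated two-class training matrix for classifier tests: `delta`
# mean shift on the first `n_inf` probes.
separable_xy <- function(n_per_class = 20, n_probes = 20, n_inf = 10,
                         delta = 3, sd = 1, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_probes * n, sd = sd), nrow = n_probes,
              dimnames = list(sprintf("g%02d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n))))
  y <- rep(c("A", "B"), each = n_per_class)
  x[seq_len(n_inf), y == "B"] <- x[seq_len(n_inf), y == "B"] + delta
  list(x = x, y = y)
}
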