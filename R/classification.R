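#' Registry of classifier training methods
#'
#' The seven classifier families: nearest shrunken centroids (`pam`),
#' lasso-penalized logistic regression (`lasso`), class-specific nearest
#' centroids (`clanc`), diagonal linear discriminant analysis (`dlda`),
#' k-nearest neighbors (`knn`), random forest (`rf`), and support vector
#' machine (`svm`).
#'
#' @return Character vector of method names.
#' @export
classifier_methods <- function() {
  c("pam", "lasso", "clanc", "dlda", "knn", "rf", "svm")
}

new_fitted_classifier <- function(method, model_state, tuning_record,
                                  probe_ids, labels) {
  structure(list(method = method, model_state = model_state,
                 tuning_record = tuning_record, probe_ids = probe_ids,
                 labels = labels),
            class = "fitted_classifier")
}

#' @export
print.fitted_classifier <- function(x, ...) {
  cat(sprintf("fitted_classifier: method=%s, %d probes, classes: %s\n",
              x$method, length(x$probe_ids), paste(x$labels, collapse = " vs ")))
  if (length(x$tuning_record$selected) > 0) {
    cat("  selected:",
        paste(names(x$tuning_record$selected), unlist(x$tuning_record$selected),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("x needs probe rownames")
  y <- as.character(y)
  if (length(y) != ncol(x)) stop("one label per sample (column) is required")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  list(x = x, y = y, labels = sort(unique(y)))
}

# ---- nearest shrunken centroids (PAM) ---------------------------------------

# Sufficient statistics for the shrunken-centroid rule.  s is the pooled
# within-class standard deviation per probe, s0 its median (the fudge
# factor), and d the standardized centroid deviations d_kg =
# (xbar_kg - xbar_g) / (m_k (s_g + s0)) with m_k = sqrt(1/n_k - 1/n).
pam_statistics <- function(x, y, labels) {
  n <- ncol(x)
  k <- length(labels)
  overall <- rowMeans(x)
  centroids <- matrix(vapply(labels,
                             function(cl) rowMeans(x[, y == cl, drop = FALSE]),
                             numeric(nrow(x))),
                      nrow = nrow(x), dimnames = list(rownames(x), labels))
  ss <- 0
  for (cl in labels) {
    dev <- x[, y == cl, drop = FALSE] - centroids[, cl]
    ss <- ss + rowSums(dev^2)
  }
  s <- sqrt(ss / (n - k))
  s0 <- stats::median(s)
  nk <- table(factor(y, levels = labels))
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- sweep(centroids - overall, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  list(overall = overall, centroids = centroids, s = s, s0 = s0,
       mk = mk, d = d, priors = as.numeric(nk) / n, labels = labels)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

pam_predict_stats <- function(stats, delta, newx) {
  dshr <- soft_threshold(stats$d, delta)
  shrunk <- stats$overall +
    sweep(sweep(dshr, 1, stats$s + stats$s0, "*"), 2, stats$mk, "*")
  denom <- (stats$s + stats$s0)^2
  scores <- vapply(seq_along(stats$labels), function(k) {
    colSums((newx - shrunk[, k])^2 / denom) - 2 * log(stats$priors[k])
  }, numeric(ncol(newx)))
  stats$labels[max.col(-matrix(scores, ncol = length(stats$labels)),
                       ties.method = "first")]
}

#' Train a nearest shrunken centroids (PAM) classifier
#'
#' Class centroids are shrunken toward the overall centroid by
#' soft-thresholding their standardized deviations at a threshold chosen
#' from a grid by seeded, stratified cross-validated misclassification
#' (ties resolved to the smallest threshold).  At threshold 0 the rule is a
#' plain standardized nearest centroid with class priors.
#'
#' @param x Numeric matrix, probes x samples, with probe rownames.
#' @param y Binary class labels, one per sample.
#' @param thresholds Threshold grid; default 30 values from 0 to the
#'   largest absolute standardized deviation.
#' @param folds Cross-validation folds for tuning (default 5).
#' @param seed Integer seed for fold assignment.
#' @return A `fitted_classifier`.
#' @export
train_pam <- function(x, y, thresholds = NULL, folds = 5, seed = 1L) {
  ck <- check_xy(x, y)
  stats_full <- pam_statistics(ck$x, ck$y, ck$labels)
  if (is.null(thresholds)) {
    thresholds <- seq(0, max(abs(stats_full$d)), length.out = 30)
  }
  cv_err <- rep(0, length(thresholds))
  if (length(thresholds) > 1) {
    fold_id <- stratified_folds(ck$y, folds, seed)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      st <- pam_statistics(ck$x[, !hold, drop = FALSE], ck$y[!hold], ck$labels)
      for (i in seq_along(thresholds)) {
        pred <- pam_predict_stats(st, thresholds[i],
                                  ck$x[, hold, drop = FALSE])
        cv_err[i] <- cv_err[i] + sum(pred != ck$y[hold])
      }
    }
    cv_err <- cv_err / length(ck$y)
  }
  best <- thresholds[which.min(cv_err)]   # ties -> smallest threshold
  new_fitted_classifier(
    "pam", model_state = c(stats_full, list(delta = best)),
    tuning_record = list(grid = thresholds, cv_error = cv_err, folds = folds,
                         seed = seed, selected = list(delta = best)),
    probe_ids = rownames(ck$x), labels = ck$labels)
}

# ---- diagonal linear discriminant analysis ----------------------------------

#' Train a diagonal linear discriminant (DLDA) classifier
#'
#' Linear discriminant with a diagonal pooled covariance: a sample is
#' assigned the class minimizing the pooled-variance-scaled squared
#' distance to the class mean.  Probes with zero pooled variance are
#' excluded with a warning.  Score ties go to the first class label in
#' sort order.
#'
#' @inheritParams train_pam
#' @return A `fitted_classifier`.
#' @export
train_dlda <- function(x, y) {
  ck <- check_xy(x, y)
  n <- ncol(ck$x)
  centroids <- matrix(vapply(ck$labels,
                             function(cl) rowMeans(ck$x[, ck$y == cl,
                                                        drop = FALSE]),
                             numeric(nrow(ck$x))),
                      nrow = nrow(ck$x),
                      dimnames = list(rownames(ck$x), ck$labels))
  ss <- 0
  for (cl in ck$labels) {
    dev <- ck$x[, ck$y == cl, drop = FALSE] - centroids[, cl]
    ss <- ss + rowSums(dev^2)
  }
  s2 <- ss / (n - length(ck$labels))
  keep <- s2 > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance probe(s) excluded from DLDA")
  }
  if (!any(keep)) stop("no probe with positive pooled variance")
  new_fitted_classifier(
    "dlda",
    model_state = list(centroids = centroids[keep, , drop = FALSE],
                       s2 = s2[keep], keep = rownames(ck$x)[keep]),
    tuning_record = list(selected = list()),
    probe_ids = rownames(ck$x), labels = ck$labels)
}

# ---- class-specific nearest centroids (ClaNC) -------------------------------

clanc_fit_fixed <- function(x, y, labels, genes_per_class) {
  st <- pam_statistics(x, y, labels)
  tsig <- st$d                 # unshrunken t-like statistic, signed
  tstat <- abs(tsig)
  p <- nrow(x)
  if (genes_per_class > p) {
    stop("genes_per_class (", genes_per_class, ") exceeds probe count (", p, ")")
  }
  # Greedy non-overlapping claim in decreasing |t|.  Between classes tied on
  # |t| for the same probe (always, for two equal-sized classes) the
  # up-regulated class wins, so selection is invariant to relabeling.  A
  # class that cannot fill its quota from unclaimed probes completes it from
  # its own ranked list.
  ord <- order(-as.vector(tstat), -as.vector(tsig),
               rep(seq_len(p), length(labels)))
  claimed <- rep(FALSE, p)
  active <- stats::setNames(vector("list", length(labels)), labels)
  quota <- stats::setNames(rep(genes_per_class, length(labels)), labels)
  for (idx in ord) {
    g <- (idx - 1) %% p + 1
    k <- labels[(idx - 1) %/% p + 1]
    if (claimed[g] || quota[[k]] == 0) next
    active[[k]] <- c(active[[k]], g)
    claimed[g] <- TRUE
    quota[[k]] <- quota[[k]] - 1
  }
  for (k in labels) {
    if (quota[[k]] > 0) {
      rest <- order(-tstat[, k], seq_len(p))
      rest <- rest[!rest %in% active[[k]]]
      active[[k]] <- c(active[[k]], rest[seq_len(quota[[k]])])
    }
  }
  used <- sort(unique(unlist(active)))
  # class centroid on its active probes, overall centroid elsewhere
  cent <- matrix(st$overall[used], nrow = length(used), ncol = length(labels),
                 dimnames = list(rownames(x)[used], labels))
  for (k in labels) {
    rows <- match(intersect(active[[k]], used), used)
    cent[rows, k] <- st$centroids[active[[k]], k]
  }
  list(used = used, centroids = cent, scale = (st$s + st$s0)[used],
       priors = st$priors, active = active)
}

clanc_predict_state <- function(state, labels, newx) {
  scores <- vapply(seq_along(labels), function(k) {
    colSums((newx[state$used, , drop = FALSE] - state$centroids[, k])^2 /
              state$scale^2) - 2 * log(state$priors[k])
  }, numeric(ncol(newx)))
  labels[max.col(-matrix(scores, ncol = length(labels)),
                 ties.method = "first")]
}

#' Train a class-specific nearest centroid (ClaNC) classifier
#'
#' Selects `genes_per_class` probes per class by a ranked t-like statistic
#' (standardized centroid deviation, unshrunken), avoiding overlap between
#' classes while unclaimed probes remain, then classifies to the nearest
#' standardized centroid built on the active probes (non-active probes of a
#' class use the overall centroid).  When `genes_per_class` is `NULL` it is
#' tuned over `c(1, 2, 5, 10, 20)` (clipped to the probe count) by seeded
#' cross-validated misclassification, ties to the smallest set.
#'
#' @inheritParams train_pam
#' @param genes_per_class Number of probes selected per class, or `NULL`
#'   to tune.
#' @return A `fitted_classifier`.
#' @export
train_clanc <- function(x, y, genes_per_class = NULL, folds = 5, seed = 1L) {
  ck <- check_xy(x, y)
  grid <- if (is.null(genes_per_class)) {
    unique(pmin(c(1, 2, 5, 10, 20), nrow(ck$x)))
  } else as.integer(genes_per_class)
  cv_err <- rep(0, length(grid))
  if (length(grid) > 1) {
    fold_id <- stratified_folds(ck$y, folds, seed)
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      for (i in seq_along(grid)) {
        st <- clanc_fit_fixed(ck$x[, !hold, drop = FALSE], ck$y[!hold],
                              ck$labels, grid[i])
        pred <- clanc_predict_state(st, ck$labels, ck$x[, hold, drop = FALSE])
        cv_err[i] <- cv_err[i] + sum(pred != ck$y[hold])
      }
    }
    cv_err <- cv_err / length(ck$y)
  }
  best <- grid[which.min(cv_err)]
  state <- clanc_fit_fixed(ck$x, ck$y, ck$labels, best)
  new_fitted_classifier(
    "clanc", model_state = state,
    tuning_record = list(grid = grid, cv_error = cv_err, folds = folds,
                         seed = seed,
                         selected = list(genes_per_class = best)),
    probe_ids = rownames(ck$x), labels = ck$labels)
}

# ---- delegated learners (lasso / knn / rf / svm) ----------------------------

default_grid <- function(method) {
  switch(method,
         lasso = list(lambda = NULL),       # glmnet's own 50-step path
         knn = list(k = c(1, 3, 5, 7, 9, 11)),
         rf = list(ntree = 500),
         svm = list(cost = c(0.01, 0.1, 1, 10)))
}

#' Train a lasso, kNN, random forest, or SVM classifier
#'
#' Thin, reproducible wrappers around established implementations
#' (\pkg{glmnet}, \pkg{class}, \pkg{randomForest}, \pkg{e1071}).
#' Hyperparameters are chosen by seeded stratified k-fold cross-validated
#' misclassification; ties resolve to the least complex setting (largest
#' lasso penalty, largest k, smallest SVM cost).  The SVM uses a linear
#' kernel.
#'
#' @inheritParams train_pam
#' @param method One of `"lasso"`, `"knn"`, `"rf"`, `"svm"`.
#' @param grid Named list of hyperparameter values; `NULL` uses the
#'   declared defaults.
#' @return A `fitted_classifier`.
#' @export
train_generic <- function(x, y, method = c("lasso", "knn", "rf", "svm"),
                          grid = NULL, folds = 5, seed = 1L) {
  method <- match.arg(method)
  ck <- check_xy(x, y)
  if (is.null(grid)) grid <- default_grid(method)
  if (length(grid) == 0) stop("hyperparameter grid must be non-empty")
  yf <- factor(ck$y, levels = ck$labels)
  xt <- t(ck$x)
  state <- NULL
  selected <- list()
  cv_err <- NULL
  switch(method,
    lasso = {
      fold_id <- stratified_folds(ck$y, folds, seed)
      lam <- grid$lambda
      fit <- if (is.null(lam)) {
        glmnet::glmnet(xt, yf, family = "binomial")
      } else {
        path <- sort(unique(c(lam, exp(seq(log(1e-4), log(10), length.out = 50)))),
                     decreasing = TRUE)
        glmnet::glmnet(xt, yf, family = "binomial", lambda = path)
      }
      cand <- if (is.null(lam)) fit$lambda else sort(lam, decreasing = TRUE)
      err <- rep(0, length(cand))
      for (f in seq_len(folds)) {
        hold <- fold_id == f
        ffit <- glmnet::glmnet(xt[!hold, , drop = FALSE], yf[!hold],
                               family = "binomial", lambda = fit$lambda)
        pred <- predict(ffit, xt[hold, , drop = FALSE], s = cand,
                        type = "class")
        err <- err + colSums(pred != ck$y[hold])
      }
      cv_err <- err / length(ck$y)
      best <- max(cand[cv_err <= min(cv_err)])   # ties -> largest penalty
      state <- list(fit = fit, lambda = best)
      selected <- list(lambda = best)
    },
    knn = {
      ks <- as.integer(grid$k)
      ks <- ks[ks <= ncol(ck$x)]
      if (length(ks) == 0) stop("no valid k in grid")
      cv_err <- rep(0, length(ks))
      if (length(ks) > 1) {
        fold_id <- stratified_folds(ck$y, folds, seed)
        for (f in seq_len(folds)) {
          hold <- fold_id == f
          for (i in seq_along(ks)) {
            pred <- with_seed(seed + f, class::knn(
              xt[!hold, , drop = FALSE], xt[hold, , drop = FALSE],
              yf[!hold], k = min(ks[i], sum(!hold))))
            cv_err[i] <- cv_err[i] + sum(pred != ck$y[hold])
          }
        }
        cv_err <- cv_err / length(ck$y)
      }
      best <- max(ks[cv_err <= min(cv_err)])     # ties -> largest k
      state <- list(train = xt, y = yf, k = best, seed = seed)
      selected <- list(k = best)
    },
    rf = {
      ntree <- if (is.null(grid$ntree)) 500 else as.integer(grid$ntree[1])
      fit <- with_seed(seed,
                       randomForest::randomForest(xt, yf, ntree = ntree))
      state <- list(fit = fit)
      selected <- list(ntree = ntree)
    },
    svm = {
      costs <- as.numeric(grid$cost)
      cv_err <- rep(0, length(costs))
      if (length(costs) > 1) {
        fold_id <- stratified_folds(ck$y, folds, seed)
        for (f in seq_len(folds)) {
          hold <- fold_id == f
          for (i in seq_along(costs)) {
            ffit <- e1071::svm(xt[!hold, , drop = FALSE], yf[!hold],
                               kernel = "linear", cost = costs[i],
                               scale = FALSE)
            pred <- predict(ffit, xt[hold, , drop = FALSE])
            cv_err[i] <- cv_err[i] + sum(pred != ck$y[hold])
          }
        }
        cv_err <- cv_err / length(ck$y)
      }
      best <- min(costs[cv_err <= min(cv_err)])  # ties -> smallest cost
      fit <- e1071::svm(xt, yf, kernel = "linear", cost = best, scale = FALSE)
      state <- list(fit = fit, cost = best)
      selected <- list(cost = best)
    })
  new_fitted_classifier(
    method, model_state = state,
    tuning_record = list(grid = grid, cv_error = cv_err, folds = folds,
                         seed = seed, selected = selected),
    probe_ids = rownames(ck$x), labels = ck$labels)
}

#' Train any registered classifier
#'
#' Dispatcher over [classifier_methods()]: `pam`, `dlda` and `clanc` are
#' fitted by the package's own implementations, `lasso`/`knn`/`rf`/`svm`
#' through [train_generic()].
#'
#' @inheritParams train_generic
#' @param method A name from [classifier_methods()].
#' @param ... Passed to the method-specific trainer.
#' @return A `fitted_classifier`.
#' @export
train_classifier <- function(x, y, method, folds = 5, seed = 1L, ...) {
  if (!method %in% classifier_methods()) {
    stop("unknown classifier '", method, "'; see classifier_methods()")
  }
  switch(method,
         pam = train_pam(x, y, folds = folds, seed = seed, ...),
         dlda = train_dlda(x, y),
         clanc = train_clanc(x, y, folds = folds, seed = seed, ...),
         train_generic(x, y, method = method, folds = folds, seed = seed, ...))
}

#' Predict class labels for new samples
#'
#' @param object A `fitted_classifier`.
#' @param newdata Numeric matrix, probes x samples, whose probe rownames
#'   match the training probe set (any order).
#' @param ... Unused.
#' @return Character vector of predicted labels, one per column.
#' @export
predict.fitted_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(rownames(newdata)) ||
      !setequal(rownames(newdata), object$probe_ids) ||
      length(rownames(newdata)) != length(object$probe_ids)) {
    stop("test probe set does not match the training probe set")
  }
  newdata <- newdata[object$probe_ids, , drop = FALSE]
  st <- object$model_state
  switch(object$method,
    pam = pam_predict_stats(st, st$delta, newdata),
    dlda = {
      xk <- newdata[st$keep, , drop = FALSE]
      scores <- vapply(seq_along(object$labels), function(k) {
        colSums((xk - st$centroids[, k])^2 / st$s2)
      }, numeric(ncol(xk)))
      object$labels[max.col(-matrix(scores, ncol = length(object$labels)),
                            ties.method = "first")]
    },
    clanc = clanc_predict_state(st, object$labels, newdata),
    lasso = as.character(predict(st$fit, t(newdata), s = st$lambda,
                                 type = "class")),
    knn = as.character(with_seed(st$seed + 7919L,
                                 class::knn(st$train, t(newdata), st$y,
                                            k = st$k))),
    rf = as.character(predict(st$fit, t(newdata))),
    svm = as.character(predict(st$fit, t(newdata))))
}

#' Cross-validated misclassification of a classifier family
#'
#' Seeded stratified k-fold cross-validation: within each fold the full
#' training procedure (including hyperparameter tuning, on a fold-derived
#' seed) is re-run on the retained samples and evaluated on the held-out
#' fold; the pooled proportion of misclassified samples is returned.
#'
#' @inheritParams train_classifier
#' @param folds Number of folds (>= 2); folds are class-stratified.
#' @return Misclassification proportion in `[0, 1]`.
#' @export
cross_validate <- function(x, y, method, folds = 5, seed = 1L, ...) {
  ck <- check_xy(x, y)
  fold_id <- stratified_folds(ck$y, folds, seed)
  wrong <- 0
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    clf <- train_classifier(ck$x[, !hold, drop = FALSE], ck$y[!hold],
                            method = method, folds = max(2, folds - 1),
                            seed = seed + 100L * f, ...)
    pred <- predict(clf, ck$x[, hold, drop = FALSE])
    wrong <- wrong + sum(pred != ck$y[hold])
  }
  wrong / length(ck$y)
}

#' External-validation misclassification
#'
#' Proportion of test samples whose predicted label differs from the truth.
#'
#' @param clf A `fitted_classifier`.
#' @param x_test Probes x samples test matrix (probe set must match
#'   training).
#' @param y_test True labels per test sample.
#' @return Misclassification proportion in `[0, 1]`.
#' @export
external_validate <- function(clf, x_test, y_test) {
  stopifnot(inherits(clf, "fitted_classifier"))
  if (length(y_test) != ncol(as.matrix(x_test))) {
    stop("one true label per test sample is required")
  }
  misclassification(predict(clf, x_test), y_test)
}
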