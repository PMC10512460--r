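#' Confusion matrix and accuracy
#'
#' @param predictions binary vector of predicted labels.
#' @param labels binary vector of true labels, same length.
#' @return list with `confusion` (2x2 integer matrix, rows = true class,
#'   cols = predicted class, in order 0, 1) and `accuracy`
#'   (`(TP + TN) / n`).
#' @export
confusion_and_accuracy <- function(predictions, labels) {
  predictions <- check_binary_labels(predictions, "predictions")
  labels <- check_binary_labels(labels)
  stopifnot(length(predictions) == length(labels), length(labels) >= 1L)
  confusion <- table(true = factor(labels, levels = c(0, 1)),
                     predicted = factor(predictions, levels = c(0, 1)))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(true = c("0", "1"),
                                      predicted = c("0", "1")))
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / length(labels))
}

new_cv_outcome <- function(predictions, labels, fold_selections, mode,
                           threshold, folds = NULL, n_fallback_folds = 0L) {
  ca <- confusion_and_accuracy(predictions, labels)
  structure(list(predictions = predictions, labels = labels,
                 accuracy = ca$accuracy, confusion = ca$confusion,
                 fold_selections = fold_selections,
                 mode = mode, threshold = threshold, folds = folds,
                 n_fallback_folds = n_fallback_folds),
            class = "cv_outcome")
}

#' @export
print.cv_outcome <- function(x, ...) {
  cat("<cv_outcome> mode ", x$mode, ", p < ", x$threshold, ": accuracy ",
      sprintf("%.3f", x$accuracy), " over ", length(x$predictions),
      " subjects\n", sep = "")
  print(x$confusion)
  invisible(x)
}

# Fit on the given training subjects and collect (not emit) any
# empty-selection fallback warning; CV summarises them once.
fit_fold <- function(data, train_idx, mode, threshold, C) {
  train <- subset_cohort(data, train_idx)
  if (length(unique(train$labels)) < 2L) {
    stop("a cross-validation fold has a single-class training set; ",
         "use stratified k-fold CV or rebalance the cohort", call. = FALSE)
  }
  fb <- FALSE
  model <- withCallingHandlers(
    fit_cpm(train, mode = mode, threshold = threshold, C = C),
    warning = function(w) {
      if (grepl("falling back to majority class", conditionMessage(w))) {
        fb <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  list(model = model, fallback = fb)
}

# Shared cross-validation engine. For each fold, the full training pipeline
# (edge-wise point-biserial correlation against the label, p-threshold
# selection, sign split, score summation, linear classifier) is rerun on the
# training subjects only; the fold's subjects are predicted with the
# training-derived masks and rule. Per-fold training sums are computed as
# crossproducts with a 0/1 training-indicator vector: held-out rows enter
# only as x * 0, so the fitted model is bit-for-bit independent of the
# held-out subjects' edge values (the no-leakage guarantee) while each fold
# costs only two BLAS calls on the full matrix.
cv_engine <- function(data, folds, mode, threshold, C, error_hint = "") {
  E <- data$edges
  y <- data$labels
  n <- nrow(E)
  nE <- ncol(E)
  K <- max(folds)
  E2 <- E * E
  predictions <- integer(n)
  fold_selections <- vector("list", K)
  n_fb <- 0L
  dirs <- if (mode == "both") c("increased", "decreased") else mode
  for (f in seq_len(K)) {
    I <- which(folds == f)
    ntr <- n - length(I)
    if (ntr < 4L) {
      stop("a fold's training set has only ", ntr,
           " subjects (need >= 4 for the selection t-test)", call. = FALSE)
    }
    ind <- rep(1, n)
    ind[I] <- 0
    ytr_sum <- sum(y * ind)
    if (ytr_sum == 0 || ytr_sum == ntr) {
      stop("a cross-validation fold has a single-class training set",
           error_hint, call. = FALSE)
    }
    sums <- crossprod(E, cbind(ind, ind * y))
    sx <- sums[, 1]
    sxy <- sums[, 2]
    sxx <- as.vector(crossprod(E2, ind))
    ybar <- ytr_sum / ntr
    ssx <- sxx - sx * sx / ntr
    ssy <- ytr_sum * (1 - ybar)       # sum(y^2) = sum(y) for 0/1 labels
    ssxy <- sxy - sx * ybar
    const <- ssx <= 0 | ssx < 1e-12 * pmax(sxx, 1)
    r <- ssxy / sqrt(pmax(ssx, .Machine$double.xmin) * ssy)
    r[const] <- 0
    r <- pmin(pmax(r, -1), 1)
    df <- ntr - 2L
    tstat <- r * sqrt(df / pmax(1 - r * r, .Machine$double.xmin))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[const] <- 1
    sel <- select_directional_features(r, pmin(p, 1), threshold)
    fold_selections[[f]] <- sel
    feats <- vapply(dirs, function(d) {
      mask <- sel[[d]]
      if (!any(mask)) rep(0, n)
      else .rowSums(E[, mask, drop = FALSE], n, sum(mask))
    }, numeric(n))
    feats <- matrix(feats, nrow = n)
    if (all(vapply(dirs, function(d) !any(sel[[d]]), logical(1)))) {
      n_fb <- n_fb + 1L
      fb <- if (ytr_sum > ntr - ytr_sum) 1L else 0L  # tie -> control
      predictions[I] <- fb
    } else {
      rule <- fast_linear_svm(feats[-I, , drop = FALSE], y[-I], C)
      predictions[I] <-
        as.integer(feats[I, , drop = FALSE] %*% rule$w + rule$b >= 0)
    }
  }
  if (n_fb > 0L) {
    warning(n_fb, " of ", K, " folds had no edges at p < ", threshold,
            " and used the majority-class fallback", call. = FALSE)
  }
  names(predictions) <- data$subject_ids
  list(predictions = predictions, fold_selections = fold_selections,
       n_fb = n_fb)
}

#' Leave-one-out cross-validation of the directional CPM
#'
#' For each subject, the entire pipeline -- edge-wise feature selection,
#' direction split, score summation, classifier fit -- is rerun on the
#' remaining n - 1 subjects and the held-out subject is predicted. Feature
#' selection therefore never sees the held-out subject (no leakage).
#'
#' @param data a [cohort_dataset()] with at least 5 subjects (every fold's
#'   training set needs n - 1 >= 4).
#' @param mode `"increased"`, `"decreased"`, or `"both"`.
#' @param threshold p-value threshold for edge selection.
#' @param C box constraint of the linear classifier.
#' @return A `cv_outcome`: out-of-fold `predictions`, `accuracy`,
#'   `confusion`, and `fold_selections` (the per-fold
#'   `directional_selection`, in subject order).
#' @export
loocv <- function(data, mode, threshold = 0.05, C = 1) {
  mode <- check_mode(mode)
  stopifnot(inherits(data, "cohort_dataset"), C > 0)
  n <- length(data$labels)
  if (n < 4L) stop("LOOCV needs at least 4 subjects; got ", n, call. = FALSE)
  eng <- cv_engine(data, seq_len(n), mode, threshold, C,
                   error_hint = "; use stratified k-fold CV or rebalance the cohort")
  new_cv_outcome(eng$predictions, data$labels, eng$fold_selections, mode,
                 threshold, folds = seq_len(n), n_fallback_folds = eng$n_fb)
}

# Stratified fold assignment: shuffle subjects within each class, then deal
# the concatenated order round-robin across folds. k = n yields singleton
# folds, i.e. the LOOCV fold structure.
make_stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  ord <- with_seed(seed, c(sample(which(labels == 0)),
                           sample(which(labels == 1))))
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

#' Stratified k-fold cross-validation
#'
#' Identical contract to [loocv()] but with k stratified folds built from a
#' seeded shuffle: subjects are shuffled within class and dealt round-robin
#' across folds, so class proportions are balanced across folds. Every
#' fold's training set must contain both classes. With `k = n` the folds are
#' singletons and the predictions coincide with LOOCV.
#'
#' @param data a [cohort_dataset()].
#' @param k number of folds (2 <= k <= n).
#' @param mode,threshold,C as in [loocv()].
#' @param seed integer seed for the fold shuffle.
#' @return A `cv_outcome`; `folds` gives each subject's fold id and
#'   `fold_selections` is indexed by fold.
#' @export
kfold_cv <- function(data, k = 10, mode, threshold = 0.05, C = 1, seed) {
  mode <- check_mode(mode)
  stopifnot(inherits(data, "cohort_dataset"))
  n <- length(data$labels)
  if (k < 2L || k > n) stop("k must be in [2, n]; got k = ", k, ", n = ", n,
                            call. = FALSE)
  folds <- make_stratified_folds(data$labels, k, seed)
  eng <- cv_engine(data, folds, mode, threshold, C,
                   error_hint = paste0("; reduce k or rebalance the cohort ",
                                       "(class sizes ", sum(data$labels == 0),
                                       "/", sum(data$labels == 1), ")"))
  new_cv_outcome(eng$predictions, data$labels, eng$fold_selections, mode,
                 threshold, folds = folds, n_fallback_folds = eng$n_fb)
}

#' Train on one cohort, test on another
#'
#' Fits the directional CPM on the entire training cohort and predicts every
#' subject of the test cohort with the training-derived masks and decision
#' rule, quantifying cross-site generalization.
#'
#' @param train,test [cohort_dataset()]s sharing node count and canonical
#'   edge order.
#' @param mode,threshold,C as in [loocv()].
#' @return A `cv_outcome` over the test subjects; `fold_selections` holds
#'   the single training-set selection.
#' @export
cross_dataset_predict <- function(train, test, mode, threshold = 0.05, C = 1) {
  mode <- check_mode(mode)
  stopifnot(inherits(train, "cohort_dataset"), inherits(test, "cohort_dataset"))
  if (ncol(train$edges) != ncol(test$edges)) {
    stop("train and test cohorts have different edge dimensions (",
         ncol(train$edges), " vs ", ncol(test$edges), ")", call. = FALSE)
  }
  fit <- fit_fold(train, seq_along(train$labels), mode, threshold, C)
  predictions <- predict_cpm(fit$model, test$edges)
  names(predictions) <- test$subject_ids
  new_cv_outcome(predictions, test$labels, list(fit$model$selection), mode,
                 threshold, n_fallback_folds = as.integer(fit$fallback))
}

#' Search the selection p-threshold by LOOCV accuracy
#'
#' Runs [loocv()] at each candidate threshold and returns the one with the
#' highest accuracy; ties are broken toward the smallest (most stringent)
#' threshold. Because the search criterion is LOOCV accuracy on the same
#' dataset, the reported best accuracy is optimistically biased; the full
#' per-threshold table is returned so this is visible.
#'
#' @param data a [cohort_dataset()].
#' @param mode direction mode.
#' @param thresholds candidate p-thresholds (default the four values
#'   0.05, 0.01, 0.005, 0.001).
#' @param C box constraint.
#' @return list with `best_threshold`, `best_outcome`, `outcomes` (named
#'   list of `cv_outcome`s) and `table` (data.frame threshold/accuracy).
#' @export
threshold_search <- function(data, mode,
                             thresholds = c(0.05, 0.01, 0.005, 0.001),
                             C = 1) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0 & thresholds < 1))
  outcomes <- lapply(thresholds, function(th) {
    loocv(data, mode = mode, threshold = th, C = C)
  })
  names(outcomes) <- as.character(thresholds)
  acc <- vapply(outcomes, function(o) o$accuracy, numeric(1))
  best_acc <- max(acc)
  best <- min(thresholds[acc == best_acc])
  list(best_threshold = best,
       best_outcome = outcomes[[as.character(best)]],
       outcomes = outcomes,
       table = data.frame(threshold = thresholds, accuracy = unname(acc)))
}

#' Add-one permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + B)`, the standard valid estimator
#' for a permutation p-value: it attains its floor `1/(B + 1)` when the
#' observed statistic beats every null draw and 1 when it beats none.
#'
#' @param observed observed statistic (here, accuracy).
#' @param null numeric vector of B null statistics.
#' @return the p-value.
#' @export
perm_p_value <- function(observed, null) {
  stopifnot(length(observed) == 1L, length(null) >= 1L)
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Label-permutation test of classification accuracy
#'
#' Builds a null distribution of accuracies by randomly shuffling the group
#' labels and rerunning the complete analysis -- including edge-wise feature
#' selection inside every fold -- for each shuffle. For the cross-dataset
#' evaluator, the training cohort's labels are shuffled and the fixed test
#' cohort is predicted. The p-value is the add-one estimator
#' [perm_p_value()]. Shuffles that make the evaluator degenerate (e.g. a
#' single-class fold) are redrawn with a message.
#'
#' @param data a [cohort_dataset()] (the training cohort for
#'   `evaluator = "cross_dataset"`).
#' @param mode,threshold,C as in [loocv()].
#' @param B number of label shuffles (default 1000).
#' @param seed integer seed governing fold assignment and all shuffles.
#' @param evaluator `"loocv"`, `"kfold"`, or `"cross_dataset"`.
#' @param k folds for the k-fold evaluator.
#' @param test test [cohort_dataset()], required for
#'   `evaluator = "cross_dataset"`.
#' @return An object of class `permutation_result`: `observed_accuracy`,
#'   `null_accuracies` (length B), `p_value`, `B`, `seed`, plus the
#'   observed `cv_outcome` in `$observed`.
#' @export
permutation_test <- function(data, mode, threshold = 0.05, C = 1, B = 1000,
                             seed, evaluator = c("loocv", "kfold",
                                                 "cross_dataset"),
                             k = 10, test = NULL) {
  evaluator <- match.arg(evaluator)
  mode <- check_mode(mode)
  stopifnot(B >= 1)
  if (evaluator == "cross_dataset" && is.null(test)) {
    stop("evaluator 'cross_dataset' requires a test cohort", call. = FALSE)
  }
  run_eval <- function(d, fold_seed) {
    suppressWarnings(switch(evaluator,
      loocv = loocv(d, mode = mode, threshold = threshold, C = C),
      kfold = kfold_cv(d, k = k, mode = mode, threshold = threshold, C = C,
                       seed = fold_seed),
      cross_dataset = cross_dataset_predict(d, test, mode = mode,
                                            threshold = threshold, C = C)))
  }
  with_seed(seed, {
    observed <- run_eval(data, draw_seed())
    null_acc <- numeric(B)
    n <- length(data$labels)
    for (b in seq_len(B)) {
      acc <- NULL
      for (attempt in 1:100) {
        perm <- sample.int(n)
        fold_seed <- draw_seed()
        shuffled <- data
        shuffled$labels <- data$labels[perm]
        acc <- tryCatch(run_eval(shuffled, fold_seed)$accuracy,
                        error = function(e) NULL)
        if (!is.null(acc)) break
        message("permutation ", b, ": degenerate shuffle redrawn (attempt ",
                attempt, ")")
      }
      if (is.null(acc)) {
        stop("could not draw a non-degenerate label shuffle after 100 attempts",
             call. = FALSE)
      }
      null_acc[b] <- acc
    }
    structure(list(observed_accuracy = observed$accuracy,
                   null_accuracies = null_acc,
                   p_value = perm_p_value(observed$accuracy, null_acc),
                   B = as.integer(B), seed = as.integer(seed),
                   evaluator = evaluator, mode = mode, threshold = threshold,
                   observed = observed),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> ", x$evaluator, ", mode ", x$mode,
      ": observed accuracy ", sprintf("%.3f", x$observed_accuracy),
      ", p = ", format(x$p_value, digits = 4), " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Exact sign test of above-chance classification
#'
#' One-sided exact binomial test that per-subject classification correctness
#' exceeds chance: with `c` of `n` subjects correctly classified,
#' `p = sum_{k >= c} choose(n, k) / 2^n`.
#'
#' @param predictions,labels binary vectors of equal length (n >= 1).
#' @return the one-sided p-value.
#' @examples
#' sign_test(c(1,1,1,1,1,1,1,1,0,0), c(1,1,1,1,1,1,1,1,1,1))  # 56/1024
#' @export
sign_test <- function(predictions, labels) {
  predictions <- check_binary_labels(predictions, "predictions")
  labels <- check_binary_labels(labels)
  stopifnot(length(predictions) == length(labels), length(labels) >= 1L)
  correct <- sum(predictions == labels)
  stats::binom.test(correct, length(labels), p = 0.5,
                    alternative = "greater")$p.value
}
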