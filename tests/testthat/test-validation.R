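test_that("confusion matrix and accuracy follow the hand counts", {
  r <- confusion_and_accuracy(c(0, 1, 1, 1), c(0, 0, 1, 1))
  expect_identical(unname(r$confusion), matrix(c(1L, 0L, 1L, 2L), 2))
  expect_equal(r$accuracy, 0.75)
  ident <- confusion_and_accuracy(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(ident$accuracy, 1)
  expect_identical(sum(ident$confusion * upper.tri(ident$confusion)) +
                     sum(ident$confusion * lower.tri(ident$confusion)), 0L)
  compl <- confusion_and_accuracy(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(compl$accuracy, 0)
  expect_identical(diag(compl$confusion), c("0" = 0L, "1" = 0L))
})

test_that("LOOCV separates planted data and is internally consistent", {
  d <- separable_cohort(seed = 12, n_per = 20, delta = 0.8)
  cv <- loocv(d, "both", threshold = 0.05)
  expect_gt(cv$accuracy, 0.9)
  expect_equal(cv$accuracy, sum(diag(cv$confusion)) / length(d$labels))
  expect_identical(sum(cv$confusion), length(d$labels))
  expect_length(cv$fold_selections, length(d$labels))
})

test_that("LOOCV rejects cohorts too small for the selection t-test", {
  edges <- matrix(rnorm(4 * 10), 4)
  d <- cohort_dataset(edges, c(0, 0, 1, 1), n_nodes = 5)
  expect_error(loocv(d, "both"), "training set has only 3")
})

test_that("k-fold CV with k = n reproduces LOOCV and is seed-deterministic", {
  d <- separable_cohort(seed = 13, n_per = 12)
  cv_loo <- loocv(d, "both", threshold = 0.05)
  cv_kn <- kfold_cv(d, k = length(d$labels), mode = "both",
                    threshold = 0.05, seed = 99)
  expect_identical(cv_kn$predictions, cv_loo$predictions)

  a <- kfold_cv(d, k = 6, mode = "both", threshold = 0.05, seed = 42)
  b <- kfold_cv(d, k = 6, mode = "both", threshold = 0.05, seed = 42)
  expect_identical(a$folds, b$folds)
  expect_identical(a$predictions, b$predictions)
  c2 <- kfold_cv(d, k = 6, mode = "both", threshold = 0.05, seed = 43)
  expect_false(identical(a$folds, c2$folds))
})

test_that("stratified folds balance classes and bad k errors", {
  d <- separable_cohort(seed = 14, n_per = 15)
  cv <- kfold_cv(d, k = 5, mode = "both", threshold = 0.05, seed = 1)
  for (f in 1:5) {
    expect_identical(sum(d$labels[cv$folds == f]), 3L)  # 15/5 patients per fold
  }
  expect_error(kfold_cv(d, k = 1, mode = "both", seed = 1), "k must be")
  expect_error(kfold_cv(d, k = 31, mode = "both", seed = 1), "k must be")
})

test_that("k-fold accuracy tracks LOOCV accuracy on planted data", {
  diffs <- vapply(1:10, function(s) {
    d <- separable_cohort(seed = 100 + s, n_per = 15, delta = 0.5)
    loo <- loocv(d, "both", threshold = 0.05)
    kf <- kfold_cv(d, k = 10, mode = "both", threshold = 0.05, seed = s)
    kf$accuracy - loo$accuracy
  }, numeric(1))
  expect_true(all(abs(diffs) <= 0.1))
})

test_that("cross-dataset prediction: resubstitution, flip complement, mismatch", {
  d <- separable_cohort(seed = 15)
  m <- fit_cpm(d, "both", threshold = 0.05)
  resub <- cross_dataset_predict(d, d, mode = "both", threshold = 0.05)
  expect_identical(unname(resub$predictions), predict_cpm(m, d$edges))
  expect_equal(resub$accuracy,
               mean(predict_cpm(m, d$edges) == d$labels))

  flipped <- d
  flipped$labels <- 1L - d$labels
  out <- cross_dataset_predict(d, flipped, mode = "both", threshold = 0.05)
  expect_equal(out$accuracy, 1 - resub$accuracy)

  small <- separable_cohort(seed = 15, n_nodes = 10)
  expect_error(cross_dataset_predict(d, small, mode = "both"),
               "different edge dimensions")
})

test_that("threshold search returns the max-accuracy threshold, ties to smallest", {
  d <- separable_cohort(seed = 16, n_per = 10, delta = 1.5)
  res <- threshold_search(d, "both")
  expect_true(res$best_threshold %in% c(0.05, 0.01, 0.005, 0.001))
  expect_equal(max(res$table$accuracy), res$best_outcome$accuracy)
  # strongly separable: every threshold reaches accuracy 1 -> smallest wins
  expect_true(all(res$table$accuracy == 1))
  expect_identical(res$best_threshold, 0.001)
})

test_that("permutation p-value formula attains its floor and ceiling", {
  expect_equal(perm_p_value(0.9, rep(0.5, 1000)), 1 / 1001)
  expect_equal(perm_p_value(0.1, runif(200, 0.4, 0.6)), 1)
  expect_equal(perm_p_value(0.5, c(0.4, 0.5, 0.6)), 3 / 4)  # ties count as >=
})

test_that("permutation test is seeded, deterministic, and small on separable data", {
  d <- separable_cohort(seed = 17, n_per = 12, delta = 1)
  p1 <- permutation_test(d, "both", threshold = 0.05, B = 30, seed = 5,
                         evaluator = "kfold", k = 6)
  p2 <- permutation_test(d, "both", threshold = 0.05, B = 30, seed = 5,
                         evaluator = "kfold", k = 6)
  expect_identical(p1$null_accuracies, p2$null_accuracies)
  expect_identical(p1$p_value, p2$p_value)
  expect_length(p1$null_accuracies, 30L)
  # perfectly separable observed accuracy beats every null: p at the floor
  expect_equal(p1$observed_accuracy, 1)
  expect_equal(p1$p_value, 1 / 31)
  expect_true(p1$p_value >= 1 / (p1$B + 1) && p1$p_value <= 1)
})

test_that("cross-dataset permutation shuffles training labels only", {
  sites <- generate_two_sites(site_design(n_controls = c(15, 15),
                                          n_patients = c(15, 15)),
                              effect_plan(n_nodes = 20, delta = 1), seed = 31)
  pr <- permutation_test(sites$site1, "decreased", threshold = 0.05, B = 25,
                         seed = 3, evaluator = "cross_dataset",
                         test = sites$site2)
  obs <- cross_dataset_predict(sites$site1, sites$site2, "decreased",
                               threshold = 0.05)
  expect_equal(pr$observed_accuracy, obs$accuracy)
  expect_equal(pr$p_value, perm_p_value(obs$accuracy, pr$null_accuracies))
  # shared decreased effects transfer near-perfectly; shuffled training
  # labels rarely do
  expect_equal(obs$accuracy, 1)
  expect_lt(pr$p_value, 0.2)
})

test_that("sign test agrees with exhaustive binomial enumeration", {
  # 8 of 10 correct: sum_{k>=8} C(10,k) / 2^10 = 56/1024
  expect_equal(sign_test(c(rep(1, 8), 0, 0), rep(1, 10)), 56 / 1024,
               tolerance = 1e-12)
  expect_equal(sign_test(c(rep(1, 5), rep(0, 5)), rep(1, 10)), 638 / 1024,
               tolerance = 1e-12)
  expect_equal(sign_test(rep(1, 12), rep(1, 12)), 2^-12, tolerance = 1e-15)
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(1:20, 1)
    labels <- rbinom(n, 1, 0.5)
    preds <- rbinom(n, 1, 0.5)
    correct <- sum(preds == labels)
    enum <- sum(choose(n, correct:n)) / 2^n
    expect_equal(sign_test(preds, labels), enum, tolerance = 1e-12)
  }
})

test_that("held-out subjects never influence their fold's fitted model", {
  d <- separable_cohort(seed = 18, n_per = 10)
  cv <- loocv(d, "both", threshold = 0.05)
  i <- 3L
  d2 <- d
  set.seed(44)
  d2$edges[i, ] <- d2$edges[i, ] + rnorm(ncol(d2$edges), sd = 5)
  cv2 <- loocv(d2, "both", threshold = 0.05)
  # fold i trains without subject i: its selection must be bit-identical
  expect_identical(cv2$fold_selections[[i]], cv$fold_selections[[i]])
})
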