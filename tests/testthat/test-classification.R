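# Gaussian discriminant analysis, grouped CV, MCC

test_that("MCC follows the standard formula and conventions", {
  expect_equal(matthews_cc(5, 5, 0, 0), 1.0)
  expect_equal(matthews_cc(0, 0, 5, 5), -1.0)
  expect_equal(matthews_cc(2, 3, 1, 1), 5 / 12)
  expect_equal(matthews_cc(3, 0, 2, 0), 0)  # zero denominator convention
  expect_error(matthews_cc(0, 0, 0, 0), "undefined")
  expect_error(matthews_cc(-1, 2, 0, 0), ">= 0")
})

test_that("the discriminant separates well-separated classes and honours priors", {
  ds <- make_two_class_features(20, means = list(-10, 10),
                                covariances = list(matrix(0.01), matrix(0.01)),
                                seed = 2)
  m <- fit_discriminant(ds)
  expect_equal(as.character(predict(m, ds$features)), as.character(ds$labels))

  # identical class distributions -> majority prior wins everywhere
  set.seed(4)
  X <- data.frame(f1 = rnorm(30))
  ds2 <- labeled_dataset(sprintf("p%d", 1:30), X,
                         c(rep("MS", 10), rep("TS", 20)))
  m2 <- fit_discriminant(ds2, mode = "linear")
  # force equal class stats so only the prior differs
  m2$class_stats$MS$mean <- m2$class_stats$TS$mean <- 0
  m2$class_stats$MS$chol <- m2$class_stats$TS$chol <- matrix(1)
  m2$class_stats$MS$logdet <- m2$class_stats$TS$logdet <- 0
  expect_true(all(predict(m2, X) == "TS"))
})

test_that("the 1-D decision threshold matches the analytic posterior-equality point", {
  # equal variances, equal priors: boundary at the midpoint of the means
  n <- 5000
  set.seed(11)
  X <- data.frame(f1 = c(rnorm(n, -1, 1), rnorm(n, 3, 1)))
  ds <- labeled_dataset(sprintf("p%d", 1:(2 * n)), X,
                        rep(c("MS", "TS"), each = n))
  m <- fit_discriminant(ds, mode = "linear")
  grid <- data.frame(f1 = seq(0, 2, by = 1e-4))
  pred <- predict(m, grid)
  flip <- grid$f1[which(pred == "TS")[1]]
  mu <- tapply(X$f1, ds$labels, mean)
  analytic <- mean(mu)  # midpoint for pooled variance, equal priors
  expect_equal(flip, analytic, tolerance = 1e-2)

  # with known parameters injected exactly, boundary matches to 1e-6
  m$class_stats$MS$mean <- c(f1 = -1); m$class_stats$TS$mean <- c(f1 = 3)
  m$class_stats$MS$chol <- m$class_stats$TS$chol <- matrix(1)
  m$class_stats$MS$logdet <- m$class_stats$TS$logdet <- 0
  m$priors <- c(MS = 0.5, TS = 0.5)
  eps <- 1e-6
  expect_equal(as.character(predict(m, data.frame(f1 = c(1 - eps, 1 + eps)))),
               c("MS", "TS"))
})

test_that("in-package discriminants agree with the MASS reference on clean data", {
  ds <- make_two_class_features(50, means = list(c(0, 0), c(2, 1)),
                                covariances = list(diag(2), diag(c(2, 0.5))),
                                seed = 7)
  mq <- fit_discriminant(ds, mode = "quadratic")
  ml <- fit_discriminant(ds, mode = "linear")
  ref_q <- MASS::qda(ds$features, ds$labels)
  ref_l <- MASS::lda(ds$features, ds$labels)
  expect_equal(as.character(predict(mq, ds$features)),
               as.character(predict(ref_q, ds$features)$class))
  expect_equal(as.character(predict(ml, ds$features)),
               as.character(predict(ref_l, ds$features)$class))
})

test_that("homology groups are never split across folds", {
  ds <- make_two_class_features(15, means = list(c(0, 0), c(1, 1)),
                                covariances = list(diag(2), diag(2)),
                                group_size = 3, seed = 9)
  set.seed(1)
  for (r in 1:100) {
    folds <- pcnfold:::assign_group_folds(ds$groups, 10)
    expect_true(all(tapply(folds, ds$groups, function(f) length(unique(f))) == 1))
  }
  expect_error(grouped_kfold_cv(ds, k = 25, n_resamplings = 2),
               "homology groups")
})

test_that("grouped CV is reproducible and stable in its summaries", {
  ds <- make_two_class_features(15, means = list(c(0, 0), c(2.5, 2.5)),
                                covariances = list(diag(2), diag(2)),
                                group_size = 1, seed = 21)
  r1 <- grouped_kfold_cv(ds, n_resamplings = 50, seed = 123)
  r2 <- grouped_kfold_cv(ds, n_resamplings = 50, seed = 123)
  expect_identical(r1, r2)  # bit-identical from the seed
  r3 <- grouped_kfold_cv(ds, n_resamplings = 50, seed = 124)
  expect_false(identical(r1$overall_accuracy, r3$overall_accuracy))

  # the resampling mean stabilises and the sd estimate is consistent
  small <- grouped_kfold_cv(ds, n_resamplings = 100, seed = 5)
  large <- grouped_kfold_cv(ds, n_resamplings = 2000, seed = 5)
  expect_lt(abs(small$overall_accuracy[["mean"]] - large$overall_accuracy[["mean"]]),
            3 * large$overall_accuracy[["sd"]] / sqrt(100) * 5 + 1)
  expect_gt(small$overall_accuracy[["sd"]], 0)
  expect_lt(abs(small$overall_accuracy[["sd"]] - large$overall_accuracy[["sd"]]),
            0.75 * large$overall_accuracy[["sd"]])
})

test_that("feature subsets of size one to four are accepted", {
  ds <- make_two_class_features(12, means = list(rep(0, 4), rep(2, 4)),
                                covariances = list(diag(4), diag(4)),
                                seed = 3)
  for (k_feat in 1:4) {
    rep_k <- grouped_kfold_cv(ds, feature_names = paste0("f", 1:k_feat),
                              k = 5, n_resamplings = 5, seed = 1)
    expect_s3_class(rep_k, "fold_cv_report")
    expect_true(is.finite(rep_k$mcc[["mean"]]))
  }
  expect_error(fit_discriminant(ds, feature_names = "nope"), "unknown feature")
})

test_that("report invariants hold: ranges and confusion totals", {
  ds <- make_two_class_features(10, means = list(0, 1.5),
                                covariances = list(matrix(1), matrix(1)),
                                seed = 33)
  rep <- grouped_kfold_cv(ds, n_resamplings = 25, k = 5, seed = 2)
  expect_true(rep$overall_accuracy[["mean"]] >= 0 &&
                rep$overall_accuracy[["mean"]] <= 100)
  expect_true(abs(rep$mcc[["mean"]]) <= 1)
  expect_equal(sum(rep$confusion_totals), 25 * 20)  # n_proteins per resampling
})
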