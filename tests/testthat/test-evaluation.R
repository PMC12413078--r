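test_that("confusion counts match hand counting and the brute-force oracle", {
  cm <- confusion(c(1, 1, -1, -1, 1), c(1, -1, -1, 1, 1))
  expect_equal(cm[c("TP", "FP", "FN", "TN")],
               list(TP = 2, FP = 1, FN = 1, TN = 1), ignore_attr = TRUE)
  y <- rep(c(1, -1), 10)
  expect_equal(unclass(confusion(y, y))[c("FP", "FN")], list(FP = 0, FN = 0))
  expect_equal(unclass(confusion(-y, y))[c("TP", "TN")], list(TP = 0, TN = 0))
  withr::with_seed(7, {
    for (rep in 1:200) {
      n <- sample(2:50, 1)
      preds <- sample(c(1, -1), n, TRUE)
      labels <- sample(c(1, -1), n, TRUE)
      cm <- confusion(preds, labels)
      oracle <- naive_confusion(preds, labels)
      expect_equal(unclass(cm)[names(oracle)], oracle, ignore_attr = TRUE)
      expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, n)
    }
  })
  expect_error(confusion(c(1, -1), 1), "length mismatch")
})

test_that("classification metrics follow the confusion-matrix formulas", {
  cm <- confusion(c(1, 1, -1, -1, 1), c(1, -1, -1, 1, 1))
  met <- classification_metrics(cm)
  expect_equal(met$accuracy, 0.6)
  expect_equal(met$precision, 2 / 3)
  expect_equal(met$recall, 2 / 3)
  expect_equal(met$f1, 2 / 3)
  expect_equal(met$specificity, 0.5)
  expect_length(met$degenerate, 0)
  # all-positive degenerate case
  cm2 <- structure(list(TP = 10, FP = 0, FN = 0, TN = 0),
                   class = "deepgam_confusion")
  met2 <- classification_metrics(cm2)
  expect_equal(met2$accuracy, 1)
  expect_equal(met2$recall, 1)
  expect_equal(met2$specificity, 0)
  expect_true("specificity" %in% met2$degenerate)
})

test_that("F1 equals the harmonic mean of precision and recall", {
  withr::with_seed(13, {
    for (rep in 1:1000) {
      cm <- structure(as.list(setNames(sample(0:20, 4, TRUE),
                                       c("TP", "FP", "FN", "TN"))),
                      class = "deepgam_confusion")
      met <- classification_metrics(cm)
      if (met$precision + met$recall > 0) {
        expect_equal(met$f1,
                     2 * met$precision * met$recall /
                       (met$precision + met$recall),
                     tolerance = 1e-12)
      } else {
        expect_equal(met$f1, 0)
      }
      for (v in c("accuracy", "precision", "recall", "f1", "specificity")) {
        expect_gte(met[[v]], 0); expect_lte(met[[v]], 1)
      }
    }
  })
})

test_that("ROC endpoints, monotonicity and extreme AUCs are correct", {
  r <- roc_and_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, -1, -1))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_and_auc(c(0.3, 0.8), c(1, -1))$auc, 0.0)
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))
  expect_error(roc_and_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  withr::with_seed(17, {
    for (rep in 1:100) {
      n <- sample(10:200, 1)
      labels <- sample(c(1, -1), n, TRUE)
      if (length(unique(labels)) < 2) labels[1:2] <- c(1, -1)
      scores <- round(rnorm(n), sample(0:2, 1)) # induce ties
      r <- roc_and_auc(scores, labels)
      expect_equal(r$auc, pair_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(19, {
    scores <- rnorm(150)
    labels <- sample(c(1, -1), 150, TRUE)
    a <- roc_and_auc(scores, labels)$auc
    expect_equal(roc_and_auc(exp(scores), labels)$auc, a, tolerance = 1e-12)
    expect_equal(roc_and_auc(atan(scores * 3), labels)$auc, a,
                 tolerance = 1e-12)
  })
})

test_that("regression metrics match the printed formulas, R2 can be negative", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(mse = 0, r2 = 1))
  expect_equal(regression_metrics(c(2, 2, 2), c(1, 2, 3))$r2, 0)
  m <- regression_metrics(c(3, 2, 1), c(1, 2, 3))
  expect_equal(m$mse, 8 / 3)
  expect_equal(m$r2, -3)
  expect_error(regression_metrics(c(1, 2), c(5, 5)), "constant")
})

test_that("cross-validation is deterministic and reports k folds", {
  sim <- make_classification(160, 2, 3, seed = 23)
  cfg <- training_config(epochs = 3, C = 8, seed = 1)
  cv1 <- cross_validate("logistic", sim$data, k = 4, seed = 2, config = cfg)
  cv2 <- cross_validate("logistic", sim$data, k = 4, seed = 2, config = cfg)
  expect_length(cv1$fold_reports, 4)
  expect_identical(cv1$mean_report, cv2$mean_report)
  expect_equal(cv1$mean_report$f1,
               mean(vapply(cv1$fold_reports, `[[`, numeric(1), "f1")))
})

test_that("a separable problem is solved perfectly in cross-validation", {
  withr::with_seed(29, {
    X <- matrix(rnorm(300 * 2), 300, 2)
    X <- X[abs(X[, 1]) > 0.2, ] # leave a clear margin
    y <- ifelse(X[, 1] > 0, 1, -1)
    ds <- deepgam_dataset(X, y)
    cv <- cross_validate("logistic", ds, k = 5, seed = 3,
                         config = training_config(seed = 1))
    expect_equal(cv$mean_report$accuracy, 1.0)
  })
})

test_that("per-fold standardizers never see held-out rows", {
  sim <- make_classification(120, 1, 2, seed = 31)
  plan <- make_folds(sim$data, 3, seed = 4)
  f <- plan$folds[[1]]
  base <- fit_standardizer(dataset_rows(sim$data, f$train))
  # inject an extreme outlier into the test fold only
  poisoned <- sim$data
  poisoned$features[f$test[1], ] <- 1e6
  poisoned <- deepgam_dataset(poisoned$features, poisoned$labels)
  after <- fit_standardizer(dataset_rows(poisoned, f$train))
  expect_identical(after$mean, base$mean)
  expect_identical(after$sd, base$sd)
})

test_that("in-fold selection retrains on fold-specific features", {
  sim <- make_classification(180, 2, 4, seed = 37)
  cfg <- training_config(epochs = 4, C = 8, seed = 1)
  cv <- cross_validate("deepgam", sim$data, k = 3, seed = 5, config = cfg,
                       selection = "lasso", select_k = 2)
  expect_length(cv$selected, 3)
  for (s in cv$selected) expect_length(s, 2)
  expect_length(cv$fold_reports, 3)
})
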