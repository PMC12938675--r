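# LOSO evaluation: fold pipeline hygiene, metric identities, Wilson
# intervals, permutation mechanics and feature importance.

test_that("Gini impurity matches direct evaluation", {
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.8, 0.2)), 0.32)
  expect_error(gini_impurity(c(0.5, 0.4)), "sum to 1")
})

test_that("duplicated feature columns are pruned to a single survivor", {
  fm <- gaussian_feature_matrix(6, 5, seed = 51)
  X <- feature_values(fm)
  X <- cbind(X, dup = X[, 1])
  colnames(X)[6] <- "F001_dup"
  res <- fold_pipeline(X[-1, ], fm$group[-1], X[1, ],
                       model_spec("decision_tree"), k_select = 3)
  expect_true("F001" %in% res$state$kept)
  expect_false("F001_dup" %in% res$state$kept)
})

test_that("selection never sees the held-out subject (leakage sentinel)", {
  fm <- gaussian_feature_matrix(6, 10, seed = 52)
  X <- feature_values(fm)
  # a feature constant in training but wildly informative on the held-out row
  X[, "F010"] <- 0
  X[1, "F010"] <- 1e6
  res <- fold_pipeline(X[-1, ], fm$group[-1], X[1, ],
                       model_spec("decision_tree"), k_select = 8)
  expect_false("F010" %in% res$state$selected)
})

test_that("a perfectly separating feature yields LOSO accuracy 1", {
  set.seed(53)
  groups <- rep(c("GD", "HC"), each = 8)
  X <- matrix(stats::rnorm(16 * 6), 16, 6)
  X[, 1] <- ifelse(groups == "GD", 5, -5) + stats::rnorm(16, 0, 0.1)
  fm <- feature_matrix_from_values(X, groups)
  res <- loso_evaluate(fm, model_spec("decision_tree", seed = 1), k_select = 3)
  expect_equal(res$accuracy, 1)
  expect_equal(res$correctness_sem, 0)
})

test_that("aggregate metrics match a brute-force confusion oracle on random predictions", {
  set.seed(54)
  for (r in 1:20) {
    y <- sample(rep(c("GD", "HC"), times = c(7, 9)))
    pred <- sample(c("GD", "HC"), 16, replace = TRUE)
    tp <- sum(y == "GD" & pred == "GD"); fn <- sum(y == "GD" & pred == "HC")
    fp <- sum(y == "HC" & pred == "GD"); tn <- sum(y == "HC" & pred == "HC")
    m <- confusion_metrics(tp, fn, fp, tn)
    expect_equal(m$accuracy, mean(y == pred))
    # independent one-vs-rest oracle
    prec <- function(cls) {
      denom <- sum(pred == cls)
      if (denom == 0) 0 else sum(pred == cls & y == cls) / denom
    }
    rec <- function(cls) {
      denom <- sum(y == cls)
      if (denom == 0) 0 else sum(pred == cls & y == cls) / denom
    }
    expect_equal(unname(m$macro_precision), mean(c(prec("GD"), prec("HC"))))
    expect_equal(unname(m$macro_recall), mean(c(rec("GD"), rec("HC"))))
  }
})

test_that("Wilson intervals bracket the point estimate and tighten with n", {
  for (k in c(0, 7, 24, 30)) {
    ci <- wilson_ci(k, 30)
    expect_true(ci["lo"] <= k / 30 && k / 30 <= ci["hi"])
    expect_true(all(ci >= 0 & ci <= 1))
  }
  expect_equal(unname(wilson_ci(0, 10)["lo"]), 0)
  w30 <- diff(wilson_ci(15, 30))
  w120 <- diff(wilson_ci(60, 120))
  expect_lt(w120, w30)
})

test_that("stochastic models are deterministic under the master seed", {
  fm <- gaussian_feature_matrix(5, 8, seed = 55, n_informative = 2, delta = 1.5)
  for (mdl in c("random_forest", "mlp")) {
    a <- loso_evaluate(fm, model_spec(mdl, seed = 99), k_select = 4)
    b <- loso_evaluate(fm, model_spec(mdl, seed = 99), k_select = 4)
    expect_identical(a$subjects$pred, b$subjects$pred)
  }
})

test_that("all five classifiers run a LOSO evaluation end to end", {
  fm <- gaussian_feature_matrix(5, 8, seed = 56, n_informative = 2, delta = 2)
  for (mdl in c("decision_tree", "random_forest", "knn", "svm_rbf", "mlp")) {
    res <- loso_evaluate(fm, model_spec(mdl, seed = 1), k_select = 4)
    expect_equal(res$n, 10)
    expect_identical(res$k, unname(res$confusion["TP"] + res$confusion["TN"]))
    expect_identical(unname(res$errors["gd_to_hc"]), unname(res$confusion["FN"]))
  }
})

test_that("misclassification table identities hold across models", {
  fm <- gaussian_feature_matrix(5, 8, seed = 57, n_informative = 1, delta = 1)
  results <- list(
    decision_tree = loso_evaluate(fm, model_spec("decision_tree", seed = 1), k_select = 4),
    knn = loso_evaluate(fm, model_spec("knn", seed = 1), k_select = 4)
  )
  tab <- misclassification_table(results)
  expect_equal(tab$total_errors, tab$gd_to_hc + tab$hc_to_gd)
  expect_equal(tab$total_errors,
               vapply(results, function(r) r$n - r$k, 0L), ignore_attr = TRUE)
  expect_equal(tab$pct_misclassified, 100 * tab$total_errors / 10)
})

test_that("on label-free data the Wilson interval covers chance in most replicates", {
  # LOSO fold outcomes share training sets, so per-subject correctness is
  # positively correlated and the binomial Wilson interval under-covers
  # relative to its nominal 95%; coverage of chance is therefore asserted
  # at a level that accounts for that overdispersion rather than at the
  # nominal rate (see the methods vignette).
  covered <- 0L
  for (r in 1:50) {
    fm <- gaussian_feature_matrix(15, 10, seed = 600 + r)
    res <- loso_evaluate(fm, model_spec("knn", seed = r), k_select = 5)
    ci <- res$wilson_ci
    covered <- covered + (ci["lo"] <= 0.5 && 0.5 <= ci["hi"])
  }
  expect_gte(covered, 35L)
})

test_that("permutation test mechanics: smoothing identity, range, B guard", {
  fm <- gaussian_feature_matrix(5, 8, seed = 58, n_informative = 2, delta = 3)
  res <- permutation_test(fm, model_spec("knn", seed = 2), B = 100, seed = 3,
                          k_select = 4)
  expect_equal(res$permutation_p,
               (1 + sum(res$null_accuracies >= res$accuracy)) / 101)
  expect_gt(res$permutation_p, 0)
  expect_lte(res$permutation_p, 1)
  expect_length(res$null_accuracies, 100)
  expect_error(permutation_test(fm, B = 50), "B must be >= 100")
})

test_that("a strong multivariate effect is declared significant by the permutation test", {
  hits <- 0L
  for (r in 1:5) {
    fm <- gaussian_feature_matrix(7, 10, seed = 700 + r,
                                  n_informative = 3, delta = 2.4)
    res <- permutation_test(fm, model_spec("decision_tree", seed = r),
                            B = 200, seed = r, k_select = 5)
    hits <- hits + (res$permutation_p < 0.05)
  }
  expect_gte(hits, 4L)
})

test_that("random-forest importance ranks a single informative feature first and normalizes", {
  hits <- 0L
  for (r in 1:10) {
    fm <- gaussian_feature_matrix(10, 15, seed = 800 + r,
                                  n_informative = 1, delta = 3)
    imp <- rank_feature_importance(fm, n_trees = 200, seed = r)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-6)
    expect_true(all(imp$importance >= 0))
    hits <- hits + (imp$feature[1] == "F001")
  }
  expect_gte(hits, 8L)
})
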