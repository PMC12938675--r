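# Leakage-safe leave-one-subject-out evaluation: per-fold z-scoring,
# Spearman collinearity pruning and ANOVA-F top-k selection fitted on the
# training subjects only; aggregate metrics with Wilson intervals; and the
# LOSO-preserving permutation test.

#' Gini impurity of a class-proportion vector
#'
#' @param p Non-negative proportions summing to 1.
#' @return `sum(p * (1 - p))`, in \[0, 1 - 1/K\].
#' @export
gini_impurity <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("proportions must be >= 0 and sum to 1", call. = FALSE)
  }
  sum(p * (1 - p))
}

#' Classifier specification
#'
#' Hyperparameters are fixed across all LOSO folds. Defaults follow the
#' conservative small-sample settings: depth-3 Gini decision tree, 100-tree
#' random forest, k = 5 Euclidean KNN, RBF SVM with C = 1 and standard
#' kernel scale, and a single-hidden-layer 16-unit ReLU MLP trained with
#' cross-entropy (500 epochs, no early stopping).
#'
#' @param model One of `"decision_tree"`, `"random_forest"`, `"knn"`,
#'   `"svm_rbf"`, `"mlp"`.
#' @param seed Master seed for stochastic models (per-fold streams are
#'   derived from it).
#' @param ... Hyperparameter overrides (`max_depth`, `n_trees`, `k`,
#'   `cost`, `hidden`, `epochs`).
#' @return A `model_spec`.
#' @export
model_spec <- function(model = c("decision_tree", "random_forest", "knn",
                                 "svm_rbf", "mlp"),
                       seed = 1L, ...) {
  model <- match.arg(model)
  defaults <- list(max_depth = 3L, n_trees = 100L, k = 5L, cost = 1.0,
                   hidden = 16L, epochs = 500L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown hyperparameters: ", paste(bad, collapse = ", "), call. = FALSE)
  defaults[names(over)] <- over
  structure(c(list(model = model, seed = seed), defaults), class = "model_spec")
}

fit_classifier <- function(spec, X, y) {
  y <- factor(y, levels = c("GD", "HC"))
  switch(spec$model,
    decision_tree = {
      df <- data.frame(y = y, X, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(maxdepth = spec$max_depth,
                                                  minsplit = 5, minbucket = 2,
                                                  cp = 0, xval = 0))
    },
    random_forest = randomForest::randomForest(X, y, ntree = spec$n_trees),
    knn = list(train = X, cl = y, k = spec$k),
    svm_rbf = e1071::svm(X, y, kernel = "radial", cost = spec$cost,
                         scale = FALSE),
    mlp = mlp_fit(X, as.integer(y == "GD"), hidden = spec$hidden,
                  epochs = spec$epochs)
  )
}

predict_classifier <- function(spec, fit, x) {
  nm <- names(x)
  x <- matrix(x, nrow = 1, dimnames = list(NULL, nm))
  switch(spec$model,
    decision_tree = {
      df <- as.data.frame(x)
      as.character(predict(fit, df, type = "class"))
    },
    random_forest = as.character(predict(fit, x)),
    knn = as.character(class::knn(fit$train, x, fit$cl, k = fit$k)),
    svm_rbf = as.character(predict(fit, x)),
    mlp = if (mlp_predict_prob(fit, x) >= 0.5) "GD" else "HC"
  )
}

# Two-group one-way ANOVA F scores, vectorized over feature columns.
# Features with zero within-group variance and zero between-group spread
# score NA; zero within-variance with distinct means scores Inf.
anova_f_scores <- function(X, y) {
  g <- y == "GD"
  n1 <- sum(g); n2 <- sum(!g); n <- n1 + n2
  m1 <- colMeans(X[g, , drop = FALSE])
  m2 <- colMeans(X[!g, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- colSums((X[g, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((X[!g, , drop = FALSE] - rep(m2, each = n2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssw == 0 & ssb > 0] <- Inf
  f[ssw == 0 & ssb == 0] <- NA_real_
  f
}

# Label-independent fold transforms: z-scoring parameters and the Spearman
# collinearity pruning, both computed from the training rows only.
fold_transforms <- function(train_X, test_x, rho_prune = 0.9) {
  mu <- colMeans(train_X)
  sd_ <- apply(train_X, 2, stats::sd)
  sd_eff <- ifelse(sd_ == 0, 1, sd_)
  Z <- sweep(sweep(train_X, 2, mu), 2, sd_eff, `/`)
  rho <- suppressWarnings(stats::cor(Z, method = "spearman"))
  p <- ncol(Z)
  keep <- rep(TRUE, p)
  for (j in seq_len(p)[-1]) {
    prior <- which(keep[seq_len(j - 1)])
    if (length(prior) && any(abs(rho[prior, j]) > rho_prune, na.rm = TRUE)) {
      keep[j] <- FALSE
    }
  }
  zt <- (test_x - mu) / sd_eff
  list(mu = mu, sd = sd_, kept = colnames(train_X)[keep],
       Z = Z[, keep, drop = FALSE], z_test = zt[keep])
}

#' One LOSO fold: fit transforms and classifier on train, predict held-out
#'
#' Stages, fitted exclusively on the training subjects: (1) per-feature
#' z-scoring; (2) Spearman collinearity pruning (`|rho| > rho_prune` drops
#' the later feature in registry order); (3) ANOVA-F top-`k_select`
#' selection; (4) classifier fit. The frozen transforms are then applied
#' to the held-out subject.
#'
#' @param train_X Training matrix (subjects x features, named columns).
#' @param train_y Training labels (`"GD"`/`"HC"`).
#' @param test_x Held-out subject's feature vector.
#' @param spec A [model_spec()].
#' @param rho_prune Spearman pruning threshold.
#' @param k_select Number of features to retain (capped at the number of
#'   pruning survivors, with a warning).
#' @param fold_seed RNG seed used for the classifier fit.
#' @return List with `pred` and `state` (a `fold_pipeline_state`: train
#'   means/SDs, retained set, selected features with F scores).
#' @export
fold_pipeline <- function(train_X, train_y, test_x, spec = model_spec(),
                          rho_prune = 0.9, k_select = 8L,
                          fold_seed = spec$seed) {
  if (min(table(factor(train_y, levels = c("GD", "HC")))) < 2) {
    stop("need >= 2 training subjects per class", call. = FALSE)
  }
  tr <- fold_transforms(train_X, test_x, rho_prune)
  f <- anova_f_scores(tr$Z, train_y)
  ok <- which(!is.na(f))
  if (k_select > length(ok)) {
    warning(sprintf("k_select = %d exceeds %d scoreable features; using all",
                    k_select, length(ok)))
  }
  k <- min(k_select, length(ok))
  sel <- ok[order(-f[ok], seq_along(f)[ok])][seq_len(k)]
  sel_names <- colnames(tr$Z)[sel]
  set.seed(fold_seed)
  fit <- fit_classifier(spec, tr$Z[, sel, drop = FALSE], train_y)
  pred <- predict_classifier(spec, fit, tr$z_test[sel])
  state <- structure(list(mu = tr$mu, sd = tr$sd, kept = tr$kept,
                          selected = sel_names, f_scores = f[sel]),
                     class = "fold_pipeline_state")
  list(pred = pred, state = state)
}

#' Fingerprint of a fold's fitted pipeline state
#' @param state A `fold_pipeline_state`.
#' @return Hash string.
#' @export
fingerprint_state <- function(state) rlang::hash(unclass(state))

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param conf Confidence level.
#' @return `c(lo, hi)`, both in \[0, 1\] and bracketing `k/n`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' SD and SEM of binary per-subject correctness
#'
#' Population-SD convention: `sd = sqrt(phat * (1 - phat))`,
#' `sem = sd / sqrt(n)`.
#'
#' @param k Correctly classified subjects.
#' @param n Subjects.
#' @return `c(sd, sem)`.
#' @export
correctness_sem <- function(k, n) {
  stopifnot(n >= 2, k >= 0, k <= n)
  p <- k / n
  sd_ <- sqrt(p * (1 - p))
  c(sd = sd_, sem = sd_ / sqrt(n))
}

#' Aggregate classification metrics from confusion counts
#'
#' GD is the positive class. Returns accuracy, per-class one-vs-rest
#' precision/recall/F1 and their macro averages.
#'
#' @param tp,fn,fp,tn Confusion counts (GD positive).
#' @return Named list of metrics.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  prf <- function(tp_, fp_, fn_) {
    prec <- if (tp_ + fp_ > 0) tp_ / (tp_ + fp_) else 0
    rec <- if (tp_ + fn_ > 0) tp_ / (tp_ + fn_) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  }
  gd <- prf(tp, fp, fn)
  hc <- prf(tn, fn, fp)
  list(accuracy = (tp + tn) / n,
       gd = gd, hc = hc,
       macro_precision = mean(c(gd["precision"], hc["precision"])),
       macro_recall = mean(c(gd["recall"], hc["recall"])),
       macro_f1 = mean(c(gd["f1"], hc["f1"])))
}

#' Leave-one-subject-out evaluation
#'
#' Runs one fold per subject (the full transform/selection/fit pipeline is
#' refitted on each fold's training subjects) and aggregates the held-out
#' predictions into confusion counts, accuracy, macro metrics, the Wilson
#' 95% interval, correctness SD/SEM and directional error counts.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param rho_prune,k_select Pipeline parameters (see [fold_pipeline()]).
#' @return A `loso_result`.
#' @export
loso_evaluate <- function(fm, spec = model_spec(), rho_prune = 0.9,
                          k_select = 8L) {
  X <- feature_values(fm)
  y <- fm$group
  n <- nrow(X)
  if (n < 4) stop("need >= 4 subjects", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  preds <- character(n)
  states <- vector("list", n)
  for (i in seq_len(n)) {
    res <- fold_pipeline(X[-i, , drop = FALSE], y[-i], X[i, ], spec,
                         rho_prune, k_select,
                         fold_seed = derive_seed(spec$seed, i))
    preds[i] <- res$pred
    states[[i]] <- res$state
  }
  loso_result(y, preds, fm$subject_id, spec, states)
}

loso_result <- function(y, preds, ids, spec, states = NULL) {
  tp <- sum(preds == "GD" & y == "GD")
  fn <- sum(preds == "HC" & y == "GD")
  fp <- sum(preds == "GD" & y == "HC")
  tn <- sum(preds == "HC" & y == "HC")
  n <- length(y)
  k <- tp + tn
  met <- confusion_metrics(tp, fn, fp, tn)
  sem <- correctness_sem(k, n)
  structure(list(
    model = spec$model,
    subjects = tibble::tibble(subject_id = ids, true = y, pred = preds,
                              correct = as.integer(preds == y)),
    confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
    n = n, k = k, accuracy = k / n,
    metrics = met,
    wilson_ci = wilson_ci(k, n),
    correctness_sd = sem[["sd"]], correctness_sem = sem[["sem"]],
    errors = c(gd_to_hc = fn, hc_to_gd = fp),
    fold_states = states,
    permutation_p = NA_real_, B = NA_integer_
  ), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %s: accuracy %.3f (%d/%d), Wilson 95%% [%.2f, %.2f], SEM %.3f\n",
              x$model, x$accuracy, x$k, x$n, x$wilson_ci["lo"],
              x$wilson_ci["hi"], x$correctness_sem))
  if (!is.na(x$permutation_p)) {
    cat(sprintf("  permutation p = %.4f (B = %d)\n", x$permutation_p, x$B))
  }
  invisible(x)
}

#' LOSO-preserving permutation test of classification accuracy
#'
#' Labels are permuted across subjects and the complete LOSO evaluation
#' (label-dependent stages: ANOVA-F selection and classifier fit) is
#' recomputed for each permutation; z-scoring and collinearity pruning do
#' not see labels and are cached per fold unchanged. The p-value uses
#' add-one smoothing: `p = (1 + #\{acc_perm >= acc_obs\}) / (B + 1)`.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param B Number of permutations (>= 100).
#' @param seed Seed for the permutation draws.
#' @param rho_prune,k_select Pipeline parameters.
#' @return A `loso_result` with `permutation_p`, `B` and
#'   `null_accuracies` filled in.
#' @export
permutation_test <- function(fm, spec = model_spec(), B = 5000L, seed = 1L,
                             rho_prune = 0.9, k_select = 8L) {
  if (B < 100) stop("B must be >= 100 (null distribution too unstable)", call. = FALSE)
  X <- feature_values(fm)
  y <- fm$group
  n <- nrow(X)
  folds <- lapply(seq_len(n), function(i) {
    fold_transforms(X[-i, , drop = FALSE], X[i, ], rho_prune)
  })
  run_loso <- function(labels) {
    preds <- character(n)
    for (i in seq_len(n)) {
      tr <- folds[[i]]
      ytr <- labels[-i]
      if (min(table(factor(ytr, levels = c("GD", "HC")))) < 2) {
        stop("permutation left < 2 training subjects in a class", call. = FALSE)
      }
      f <- anova_f_scores(tr$Z, ytr)
      ok <- which(!is.na(f))
      kk <- min(k_select, length(ok))
      sel <- ok[order(-f[ok], seq_along(f)[ok])][seq_len(kk)]
      set.seed(derive_seed(spec$seed, i))
      fit <- fit_classifier(spec, tr$Z[, sel, drop = FALSE], ytr)
      preds[i] <- predict_classifier(spec, fit, tr$z_test[sel])
    }
    preds
  }
  obs_preds <- run_loso(y)
  acc_obs <- mean(obs_preds == y)
  set.seed(seed)
  perms <- replicate(B, sample(y))
  acc_null <- numeric(B)
  for (b in seq_len(B)) {
    yb <- perms[, b]
    acc_null[b] <- mean(run_loso(yb) == yb)
  }
  p <- (1 + sum(acc_null >= acc_obs)) / (B + 1)
  out <- loso_result(y, obs_preds, fm$subject_id, spec)
  out$permutation_p <- p
  out$B <- as.integer(B)
  out$null_accuracies <- acc_null
  out
}

#' Directional misclassification summary across models
#'
#' @param results Named list of `loso_result`s on the same cohort.
#' @return Tibble: model, total errors, GD->HC, HC->GD, % misclassified.
#' @export
misclassification_table <- function(results) {
  rows <- lapply(names(results), function(m) {
    r <- results[[m]]
    tibble::tibble(model = m,
                   total_errors = r$n - r$k,
                   gd_to_hc = unname(r$errors["gd_to_hc"]),
                   hc_to_gd = unname(r$errors["hc_to_gd"]),
                   pct_misclassified = 100 * (r$n - r$k) / r$n)
  })
  do.call(rbind, rows)
}

#' Random-Forest Gini importance ranking
#'
#' Descriptive importance of each feature from a forest trained on the
#' full matrix (not part of the LOSO selection pipeline); importances are
#' normalized to sum to 1 and returned in descending order.
#'
#' @param fm A `feature_matrix`.
#' @param n_trees Forest size.
#' @param seed RNG seed.
#' @return Tibble with `feature`, `importance`.
#' @export
rank_feature_importance <- function(fm, n_trees = 500L, seed = 1L) {
  X <- feature_values(fm)
  y <- factor(fm$group, levels = c("GD", "HC"))
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = n_trees, importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  out <- tibble::tibble(feature = names(imp), importance = unname(imp))
  out[order(-out$importance), ]
}
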