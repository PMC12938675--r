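#!/usr/bin/env Rscript
# Stage 4: leakage-safe LOSO evaluation of the five classifiers.
#
# Reads the stage-2 concatenated feature matrix and evaluates the
# decision tree, random forest, KNN, RBF-SVM and ReLU-MLP under
# leave-one-subject-out cross-validation (per-fold z-scoring, Spearman
# pruning at |rho| > 0.9 and ANOVA-F top-8 selection, all fitted on the
# training subjects only). The decision tree and KNN additionally get a
# LOSO-preserving permutation test (B = 1000 here; scale B up for
# publication-grade p-values). Writes the aggregate metric table, the
# directional misclassification table, and per-model confusion counts.

library(gdeeg)

seed <- 42
out_dir <- "results"
fm_path <- file.path(out_dir, "features_concatenated.csv")
if (!file.exists(fm_path)) {
  stop("missing ", fm_path, " - run analysis/02_features.R first")
}
df <- read.csv(fm_path, check.names = FALSE)
fm <- feature_matrix_from_values(as.matrix(df[, -(1:3)]), df$group,
                                 df$subject_id)

models <- c("decision_tree", "random_forest", "knn", "svm_rbf", "mlp")
results <- list()
for (m in models) {
  message("LOSO: ", m)
  spec <- model_spec(m, seed = seed)
  if (m %in% c("decision_tree", "knn")) {
    results[[m]] <- permutation_test(fm, spec, B = 1000L, seed = seed)
  } else {
    results[[m]] <- loso_evaluate(fm, spec)
  }
  print(results[[m]])
}

metrics <- do.call(rbind, lapply(names(results), function(m) {
  r <- results[[m]]
  data.frame(model = m, accuracy = r$accuracy, k = r$k, n = r$n,
             sem = r$correctness_sem,
             wilson_lo = r$wilson_ci[["lo"]], wilson_hi = r$wilson_ci[["hi"]],
             macro_precision = r$metrics$macro_precision,
             macro_recall = r$metrics$macro_recall,
             macro_f1 = r$metrics$macro_f1,
             permutation_p = r$permutation_p, B = r$B)
}))
write.csv(metrics, file.path(out_dir, "model_metrics.csv"), row.names = FALSE)
write.csv(misclassification_table(results),
          file.path(out_dir, "misclassification.csv"), row.names = FALSE)
conf <- do.call(rbind, lapply(names(results), function(m) {
  data.frame(model = m, t(results[[m]]$confusion))
}))
write.csv(conf, file.path(out_dir, "confusions.csv"), row.names = FALSE)
message("wrote ", out_dir, "/model_metrics.csv, misclassification.csv, confusions.csv")
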