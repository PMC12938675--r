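#!/usr/bin/env Rscript
# Stage 3: effect-size screening and feature relevance.
#
# Reads the stage-2 feature matrices and screens every feature with
# Welch's t, BH-FDR adjustment, Cohen's d (signed GD - HC) and the
# Spearman correlation with the group label; a Random-Forest Gini
# importance ranking is computed descriptively on the full matrix. With
# the default effect profile the top of the |d| ranking is dominated by
# slow-wave (Delta/Theta) amplitude and shape features, reflecting the
# injected spectral-slowing contrast.

library(gdeeg)

out_dir <- "results"
fm_path <- file.path(out_dir, "features_concatenated.csv")
if (!file.exists(fm_path)) {
  stop("missing ", fm_path, " - run analysis/02_features.R first")
}

read_fm <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  feature_matrix_from_values(as.matrix(df[, -(1:3)]), df$group,
                             df$subject_id, df$aggregation_mode[1])
}

for (mode in c("concatenated", "segmentwise")) {
  path <- file.path(out_dir, paste0("features_", mode, ".csv"))
  if (!file.exists(path)) next
  fm <- read_fm(path)
  et <- effect_table(fm)
  write.csv(et, file.path(out_dir, paste0("effects_", mode, ".csv")),
            row.names = FALSE)
  message("top effects (", mode, "):")
  print(head(et[, c("feature", "mean_GD", "mean_HC", "p", "p_fdr", "cohens_d")], 5))
}

fm <- read_fm(fm_path)
lc <- label_correlations(fm)
write.csv(lc, file.path(out_dir, "label_correlations.csv"), row.names = FALSE)

imp <- rank_feature_importance(fm, n_trees = 500, seed = 42)
write.csv(imp, file.path(out_dir, "rf_importance.csv"), row.names = FALSE)
message("top-10 Random-Forest importances:")
print(head(imp, 10))
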