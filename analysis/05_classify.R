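#!/usr/bin/env Rscript
# Stage 5: valence classification.
#
# Three passes, all under participant-grouped cross-validation with the
# fixed seed 1004:
#   (a) pooled (uncontrolled) run over all valid trials;
#   (b) arousal x spatial-frequency stratified grid, best configuration
#       per cell selected both by mean AUC and by mean P4;
#   (c) the best cell re-run with fold-internal SMOTE (k = 5) and its
#       mean ROC curve.
# The classifier set here is kept small (logistic regression plus two
# tree ensembles) so the stage runs in minutes; the full eleven-model
# roster is available through classifier_roster().

suppressPackageStartupMessages(library(pupilvalence))

tab <- read_features("results/features.csv")
message("records: ", nrow(tab))

## (a) pooled run
pooled <- run_cv(tab, run_config(cv_folds = 5L,
                                 classifier_name = "logistic"))
message("pooled group 5-fold logistic:")
print(pooled$summary)
write_metrics_json(pooled, "results/pooled_run.json")

## (b) stratified grid
grid <- grid_run(tab, run_config(),
                 classifiers = c("logistic", "random_forest", "lightgbm"),
                 smote_k = NA_integer_, folds = 5L)
readr::write_csv(grid$cells, "results/grid_cells.csv")
readr::write_csv(grid$best$by_auc, "results/grid_best_by_auc.csv")
readr::write_csv(grid$best$by_p4, "results/grid_best_by_p4.csv")
readr::write_csv(grid$p4_table, "results/grid_p4_heatmap.csv")
if (nrow(grid$absent) > 0) readr::write_csv(grid$absent,
                                            "results/grid_absent.csv")
top <- grid$best$by_auc[which.max(grid$best$by_auc$mean_auc), ]
message(sprintf(
  "best stratified cell: arousal %s x SF %d, %s, mean AUC %.3f (pooled %.3f)",
  top$arousal_level, top$sf_level, top$model, top$mean_auc,
  pooled$summary$mean[pooled$summary$metric == "auc"]
))

## (c) best cell with fold-internal SMOTE + mean ROC
cell <- tab[tab$arousal_level == top$arousal_level &
              tab$sf_level == top$sf_level, ]
cell_cv <- run_cv(cell, run_config(cv_folds = 5L,
                                   classifier_name = "logistic",
                                   smote_k_neighbors = 5L))
message(sprintf("best cell + SMOTE(k=5) logistic: mean AUC %.3f +- %.3f",
                cell_cv$roc$mean_auc, cell_cv$roc$sd_auc))
write_metrics_json(cell_cv, "results/best_cell_smote_run.json")
readr::write_csv(cell_cv$roc$curve, "results/best_cell_mean_roc.csv")
message("wrote classification tables under results/")
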