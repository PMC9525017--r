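#!/usr/bin/env Rscript
# Stage 2 — train the global and regional brain-age models.
#
# RBF support-vector regression per scope: the global model on the 40
# region-mean GMV features, one regional model per region on its ten
# voxel features. Hyperparameters are grid-searched by 5-fold CV; model
# accuracy is reported as out-of-fold MAE and R^2.

suppressMessages(library(csvdbag))

seed <- 20260101L
indir <- "results/cohorts"
outdir <- "results/models"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cond <- demo_conditions(seed = seed)
atlas <- read_atlas_json(file.path(indir, "atlas.json"))
subjects <- read_table_tsv(file.path(indir, "train_subjects.tsv"))
features <- read_feature_table(file.path(indir, "train_features.tsv"), atlas)

cat("training global model on region means ...\n")
global <- fit_global_model(features, subjects$age, cond$model,
                           nested = FALSE)
cat(sprintf("  global: C = %g, gamma = %g, CV MAE = %.2f y, R^2 = %.3f\n",
            global$cost, global$gamma, global$cv$pooled_mae,
            global$cv$pooled_r2))

cat("training", atlas$n_regions, "regional models on voxel features ...\n")
regional <- fit_regional_models(features, subjects$age, atlas, cond$model,
                                nested = FALSE)
r2 <- vapply(regional, function(m) m$cv$pooled_r2, numeric(1))
mae_r <- vapply(regional, function(m) m$cv$pooled_mae, numeric(1))
cat(sprintf("  regional R^2 range: %.3f-%.3f; MAE range: %.2f-%.2f y\n",
            min(r2), max(r2), min(mae_r), max(mae_r)))

cv_table <- data.frame(region_id = names(regional), cv_mae = mae_r,
                       cv_r2 = r2, row.names = NULL)
write_table_tsv(cv_table, file.path(outdir, "regional_cv_metrics.tsv"))
saveRDS(list(global = global, regional = regional),
        file.path(outdir, "models.rds"))
cat("wrote model bundle and CV metrics to", outdir, "\n")
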