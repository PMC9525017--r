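#!/usr/bin/env Rscript
# Stage 3 — estimate brain-age gaps and classify CSVD.
#
# The frozen models are applied (no refitting) to the application cohort;
# BAG = predicted - chronological age per scope. CSVD is classified by the
# marker rule: WMH/TIV ratio at or above the cohort median AND at least
# one lacune or microbleed.

suppressMessages(library(csvdbag))

indir <- "results/cohorts"
outdir <- "results/bag"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

atlas <- read_atlas_json(file.path(indir, "atlas.json"))
subjects <- read_table_tsv(file.path(indir, "app_subjects.tsv"))
features <- read_feature_table(file.path(indir, "app_features.tsv"), atlas)
models <- readRDS("results/models/models.rds")

bag <- predict_and_bag(models, features, subjects$age)
write_table_tsv(bag, file.path(outdir, "bag.tsv"),
                units = list(predicted_age = "years", bag = "years"))

markers <- subjects[c("subject_id", "wmh_volume", "tiv_ml",
                      "lacune_count", "cmb_count")]
names(markers)[names(markers) == "tiv_ml"] <- "tiv"
cls <- classify_csvd(markers)
write_table_tsv(cls$flags, file.path(outdir, "csvd_flags.tsv"))
jsonlite::write_json(list(threshold = cls$threshold, rule = cls$rule),
                     file.path(outdir, "csvd_rule.json"),
                     auto_unbox = TRUE, digits = NA)

smry <- csvd_subgroup_summary(markers, cls$flags)
cat(sprintf("WMH/TIV median threshold: %.2e\n", cls$threshold))
cat(sprintf("CSVD group: %d of %d subjects (%.1f%%)\n",
            sum(cls$flags$csvd), nrow(subjects),
            100 * mean(cls$flags$csvd)))
for (i in seq_len(nrow(smry))) {
  cat(sprintf("  %s: %d (%.1f%%)\n", smry$marker[i], smry$n[i],
              smry$pct[i]))
}
gb <- bag$bag[bag$scope == "global"]
cat(sprintf("global BAG: CSVD %.2f +/- %.2f y, non-CSVD %.2f +/- %.2f y\n",
            mean(gb[cls$flags$csvd]), sd(gb[cls$flags$csvd]),
            mean(gb[!cls$flags$csvd]), sd(gb[!cls$flags$csvd])))
cat("wrote BAG table and CSVD flags to", outdir, "\n")
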