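#!/usr/bin/env Rscript
# Stage 5 — BCa-bootstrap mediation screen.
#
# For every region flagged in stage 4 and each cognitive outcome: does
# that region's BAG mediate the CSVD-cognition association? Covariates
# (age, age^2, sex, education, EFC, TIV) enter all three path models;
# inference on a, b and a*b uses the bias-corrected and accelerated
# bootstrap. A mediation is declared when all three paths reach p < 0.05.

suppressMessages(library(csvdbag))

seed <- 20260101L
indir <- "results/cohorts"
outdir <- "results/mediation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

subjects <- read_table_tsv(file.path(indir, "app_subjects.tsv"))
bag <- read_table_tsv("results/bag/bag.tsv")
class(bag) <- c("bag_result", "data.frame")
flags <- read_table_tsv("results/bag/csvd_flags.tsv")
group <- as.integer(flags$csvd[match(subjects$subject_id,
                                     flags$subject_id)])
cmp <- read_table_tsv("results/comparison/regional_comparison.tsv")
regions <- cmp$region_id[cmp$significant]

tab <- mediation_screen(bag, subjects, group, regions,
                        outcomes = c("mmse", "cvvlt", "vft"),
                        B = 1000, alpha = 0.05, seed = seed + 41L,
                        fwer = TRUE)
write_table_tsv(tab, file.path(outdir, "mediation.tsv"))
jsonlite::write_json(list(B = 1000, alpha = 0.05, seed = seed + 41L,
                          fwer = "bonferroni", n_models = nrow(tab)),
                     file.path(outdir, "run_metadata.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("screened %d (region, outcome) models over %d regions\n",
            nrow(tab), length(regions)))
sig <- tab[tab$significant, ]
if (nrow(sig) == 0) {
  cat("no significant mediations at p < 0.05 on all three paths\n")
} else {
  for (i in seq_len(nrow(sig))) {
    cat(sprintf(
      "  %s -> %s: a*b = %.2f (p = %.3g), proportion mediated = %.0f%%\n",
      sig$region[i], sig$outcome[i], sig$ab[i], sig$p_ab[i],
      sig$prop_mediated[i]))
  }
}
truth <- jsonlite::read_json(file.path(indir, "ground_truth.json"),
                             simplifyVector = TRUE)
planted <- names(truth$b_m$mmse)
cat(sprintf("planted mediator: %s on mmse (true proportion mediated 80%%)\n",
            paste(planted, collapse = ", ")))
cat("wrote mediation table to", outdir, "\n")
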