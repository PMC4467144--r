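#!/usr/bin/env Rscript
# Evaluate the seven-gene low-expression panel as a classifier of locally
# invasive (pT3) tumours over the percentile/k cut-off grid: bottom 10% of
# at least 1 gene, bottom 25% of at least 2, bottom 50% of at least 4.

suppressPackageStartupMessages(library(pea3targets))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)
dir.create("results", showWarnings = FALSE)

truth <- planted_truth(100, roles = c(stage_low_in_pT3 = 7,
                                      gleason_assoc = 3, pea3_up = 2),
                       lfc = 1.5, noise_sd = 0.4)
cohort <- gen_tumor_cohort(truth, seed = seed + 2L)
panel <- planted_genes(truth, "stage_low_in_pT3")

scan <- cutoff_scan(cohort, panel)
write_panel_evaluation(scan$table, "results/panel_scan.tsv")

cat("panel cut-off scan (ranked by chi-square p):\n")
print(scan$table, row.names = FALSE, digits = 4)
best <- scan$table[1, ]
cat(sprintf(
  "best rule: bottom %g%% of >= %d genes -> p = %.2g, sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%\n",
  best$q, best$k, best$p, 100 * best$sensitivity, 100 * best$specificity,
  100 * best$ppv, 100 * best$npv))
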