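#!/usr/bin/env Rscript
# Simulate the study's three datasets with planted ground truth and write
# them under results/data/: (i) the five-model cell-line experiment carrying
# the target-gene regime (13 ETV1-specific / 26 ETV4-specific / 24 shared,
# 2 inverse-overlap, 1000 nulls), (ii) the same experiment carrying the
# phenotype regime (81 invasion-and/or-AIG / 17 AIG / 27 invasion), and
# (iii) the 9 NPT + 50 PCa cohort with the seven-gene stage panel planted.

suppressPackageStartupMessages(library(pea3targets))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

target_truth <- planted_truth(
  1061, roles = c(ETV1_target_up = 5, ETV1_target_down = 6,
                  ETV4_target_up = 9, ETV4_target_down = 15,
                  shared_up = 8, shared_down = 16, inverse = 2),
  lfc = 1.0, noise_sd = 0.1)
expt <- gen_cellline_experiment(target_truth, seed = seed)
write_expression_matrix(expt$exprs, "results/data/cellline_targets.tsv")

pheno_truth <- planted_truth(
  1125, roles = c(invasion_or_aig_assoc = 81, aig_assoc = 17,
                  invasion_assoc = 27),
  lfc = 1.0, noise_sd = 0.05)
pheno <- gen_cellline_experiment(pheno_truth, seed = seed + 1L)
write_expression_matrix(pheno$exprs, "results/data/cellline_phenotype.tsv")

cohort_truth <- planted_truth(100, roles = c(stage_low_in_pT3 = 7,
                                             gleason_assoc = 3, pea3_up = 2),
                              lfc = 1.5, noise_sd = 0.4)
cohort <- gen_tumor_cohort(cohort_truth, seed = seed + 2L)
write_expression_matrix(cohort$exprs, "results/data/cohort_expression.tsv")
write_annotations(cohort$annotations, "results/data/cohort_annotations.tsv")

an <- cohort$annotations
cat(sprintf("cell-line experiments: %d and %d genes x %d arrays\n",
            nrow(expt$exprs), nrow(pheno$exprs), ncol(expt$exprs)))
cat(sprintf("cohort: %d NPT + %d PCa (PEA3 %d / ERG %d / ETS-negative %d); %d pT3 / %d pT2\n",
            sum(an$tissue == "NPT"), sum(an$tissue == "PCa"),
            sum(an$subtype == "PEA3", na.rm = TRUE),
            sum(an$subtype == "ERG", na.rm = TRUE),
            sum(an$subtype == "ETS_negative", na.rm = TRUE),
            sum(an$stage == "pT3", na.rm = TRUE),
            sum(an$stage == "pT2", na.rm = TRUE)))
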