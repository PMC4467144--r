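#!/usr/bin/env Rscript
# Filter the phenotype-regime experiment into invasion- and AIG-associated
# gene sets via the include/exclude fold-change cascade over the models with
# and without phenotypic impact.

suppressPackageStartupMessages(library(pea3targets))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed"))) args[i + 1] else 1)
dir.create("results", showWarnings = FALSE)

truth <- planted_truth(
  1125, roles = c(invasion_or_aig_assoc = 81, aig_assoc = 17,
                  invasion_assoc = 27),
  lfc = 1.0, noise_sd = 0.05)
expt <- gen_cellline_experiment(truth, seed = seed + 1L)
profile <- build_association_profile(expt$models, expt$exprs)
report <- build_phenotype_report(profile)
write_gene_set_report(report, "results/phenotype_sets.tsv")

s <- report$summary
cat(sprintf("invasion and/or AIG (|FC| > 1.2 in 3 models, not in shETV1-MDA): %d genes\n",
            s["invasion_or_aig"]))
cat(sprintf("AIG (|FC| > 1.5 in both shETV4 models): %d genes\n", s["aig"]))
cat(sprintf("invasion (|FC| > 1.5 in shETV1-LNCaP and PNT2-ETV1): %d genes\n",
            s["invasion"]))
cat(sprintf("overlaps: AIG-in-union %d, invasion-in-union %d, AIG/invasion %d\n",
            s["aig_in_union"], s["invasion_in_union"],
            s["aig_invasion_overlap"]))
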