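#!/usr/bin/env Rscript
# Simulate the study cohorts: a "cancer-like" cohort with planted expression
# tails and a matched methylation link, and a symmetric "control" cohort on
# the same gene space. All downstream analyses read the TSV/GMT artifacts
# written here.

suppressPackageStartupMessages(library(skewcohort))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg_cancer <- cohort_config(
  n_genes = 1000, n_samples = 300,
  tail_fraction = 0.1, tail_shift = 3,
  baseline_mean_sd = 2,
  fraction_negative_skew = 0.5,
  linked_fraction = 0.2, target_corr = -0.8,
  methyl_shift = c(Promoter = -1, UTR = 0, Body = 0),
  seed = 101
)
cancer <- generate_cohort(cfg_cancer)

cfg_control <- cohort_config(
  n_genes = 1000, n_samples = 300,
  tail_fraction = 0, tail_shift = 0,
  baseline_mean_sd = 2,
  seed = 102
)
control <- generate_cohort(cfg_control)

write_matrix(cancer$expression, "results/data/expr_cancer.tsv", "gene_id")
write_matrix(control$expression, "results/data/expr_control.tsv", "gene_id")
write_matrix(cancer$methylation, "results/data/meth_cancer.tsv", "probe_id")
write.table(cancer$annotation, "results/data/probe_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt(cancer$gene_sets, "results/data/gene_sets.gmt")
jsonlite::write_json(cancer$truth$genes, "results/data/truth_cancer.json",
                     dataframe = "rows", digits = NA)

truth <- cancer$truth$genes
cat("Simulated cohorts written to results/data/\n")
cat(sprintf("  cancer: %d genes x %d samples; %d linked genes (%.0f%%)\n",
            nrow(cancer$expression), ncol(cancer$expression),
            sum(truth$linked), 100 * mean(truth$linked)))
cat(sprintf("  planted skew: %.0f%% negative, tail fraction %.2f, shift %.1f sd\n",
            100 * mean(truth$direction < 0), cfg_cancer$tail_fraction,
            cfg_cancer$tail_shift))
cat(sprintf("  control: %d genes x %d samples, symmetric\n",
            nrow(control$expression), ncol(control$expression)))
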