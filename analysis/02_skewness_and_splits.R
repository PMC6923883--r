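#!/usr/bin/env Rscript
# Per-gene skewness in both cohorts, gene splitting, the size of the bias
# correction, a platform-style comparison of split groups, and the
# skewness-vs-mean diagnostic.

suppressPackageStartupMessages(library(skewcohort))

dir.create("results", showWarnings = FALSE)
cancer <- read_matrix("results/data/expr_cancer.tsv", "expression")
control <- read_matrix("results/data/expr_control.tsv", "expression")

sk_cancer <- compute_skewness(cancer)
sk_control <- compute_skewness(control)
write.table(sk_cancer, "results/skew_cancer.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sk_control, "results/skew_control.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sp_cancer <- gene_split(sk_cancer)
sp_control <- gene_split(sk_control)
cat(sprintf("Gene split (fraction negative skew): cancer %.3f, control %.3f\n",
            sp_cancer$fraction_negative, sp_control$fraction_negative))
cat(sprintf("Bias correction at n=%d: %.4f%% (negligible)\n",
            ncol(cancer), 100 * correction_magnitude(ncol(cancer))))

# platform-style comparison: subsampled replicate splits per cohort stand in
# for groups of datasets measured on two platforms
set.seed(23)
splits_a <- replicate(6, gene_split(compute_skewness(
  cancer[, sample(ncol(cancer), 150)]))$fraction_negative)
splits_b <- replicate(6, gene_split(compute_skewness(
  control[, sample(ncol(control), 150)]))$fraction_negative)
cmp <- compare_splits(splits_a, splits_b)
# a strongly planted cohort can have an identical split in every subsample,
# in which case its Shapiro p is undefined
fmt_p <- function(p) if (is.na(p)) "constant group" else sprintf("%.3f", p)
cat(sprintf("Welch t = %.3f (p = %.2e); Shapiro p: %s / %s\n",
            cmp$t_statistic, cmp$p_value, fmt_p(cmp$shapiro_p_a),
            fmt_p(cmp$shapiro_p_b)))

diag <- skew_vs_mean_diagnostic(sk_cancer, n_bins = 10)
write.table(diag, "results/skew_vs_mean.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Skewness vs mean expression: overall r = %.3f; median per-bin |r| = %.3f\n",
            attr(diag, "overall_r"), median(abs(diag$r), na.rm = TRUE)))
cat("The statistic is shift/scale invariant, so any residual association\n")
cat("reflects the planted tails shifting gene means, not the measure itself.\n")
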