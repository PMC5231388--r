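#!/usr/bin/env Rscript

# Genomic-control inflation from intergenic SNPs: median squared z-score of
# LD-pruned intergenic sets over 100 pruning iterations, divided by the
# chi-square(1) median.

source("analysis/00_study.R")

s <- build_study()
lam <- estimate_lambda(s$stats, s$score_table$intergenic, s$nbhd,
                       n_iter = 100, seed = 1L)
write_lambda_report(lam, file.path(results_dir, "03_lambda.json"))

print(lam)
cat(sprintf("Per-iteration medians: %.4f-%.4f (IQR %.4f)\n",
            min(lam$per_iteration_medians), max(lam$per_iteration_medians),
            IQR(lam$per_iteration_medians)))
cat("\nThe study plants no cryptic-relatedness inflation; the residual\n")
cat("excess over 1 reflects true polygenic signal reaching intergenic SNPs\n")
cat("through the baseline per-SNP heritability, not test-statistic bias.\n")
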