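#!/usr/bin/env Rscript

## Stage 3: bootstrap network performance across the standard input sets.
##
## For every predictor set in the catalogue, repeats the randomized
## 75/25 train/validation evaluation (default 200 runs here; pass a
## different count as the first argument) and reports mean chi-squared
## concordance, its 95% CI, and Cramér's V. The best-performing set is
## then compared against its surrogate permutation null with the KS
## test, and the multinomial logistic-regression baseline is evaluated on
## the same seeds for that set.

suppressPackageStartupMessages(library(hbnet))

args <- commandArgs(trailingOnly = TRUE)
n_runs <- if (length(args) >= 1) as.integer(args[1]) else 200L

cohort <- read_cohort("results/cohort.csv")
cfg <- eval_config(n_runs = n_runs, root_seed = 1L)

perf <- performance_report(cohort, standard_input_sets(), cfg)
write_report(perf, "results/table_performance.csv")
cat("network performance (results/table_performance.csv):\n")
print(perf[, c("label", "mean_chi2", "ci_low", "ci_high", "cramers_v",
               "effect_size")], digits = 3, row.names = FALSE)

best_name <- perf$input_set[which.max(perf$mean_chi2)]
best <- get_input_sets(best_name)[[1]]
cat("\nbest input set:", best$label, "\n")

null_res <- evaluate_with_null(cohort, best, cfg)
cat(sprintf("real vs surrogate chi2: mean %.1f vs %.1f; ",
            null_res$summary$mean_chi2, mean(null_res$surrogate)))
print(null_res$comparison)

lrm_perf <- bootstrap_evaluate(cohort, best, cfg, estimator = "lrm")
cat("\nlogistic-regression baseline on the same input set:\n")
print(lrm_perf)
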