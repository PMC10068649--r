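#!/usr/bin/env Rscript

## Stage 4: subgroup analyses.
##
## (a) Tumor size: per-run chi-squared concordance within each Koos
##     group (complete sample per run), with the linear model of group
##     chi-squared on tumor size and group patient count.
## (b) Separate intermediate nerve: full-sample comparison of the NI and
##     non-NI strata with the KS test, and the validation-split
##     comparison of corrected vs uncorrected traintime by stratum.

suppressPackageStartupMessages(library(hbnet))

args <- commandArgs(trailingOnly = TRUE)
n_runs <- if (length(args) >= 1) as.integer(args[1]) else 200L

cohort <- read_cohort("results/cohort.csv")
cfg <- eval_config(n_runs = n_runs, root_seed = 1L)
best <- get_input_sets("traintime_nocluster_koos_preop")[[1]]

## (a) Koos subgroups
by_koos <- subgroup_evaluate(cohort, best, cfg, grouping = "koos")
koos_tab <- do.call(rbind, lapply(names(by_koos$groups), function(g) {
  s <- by_koos$groups[[g]]
  data.frame(group = g, mean_chi2 = s$mean_chi2, ci_low = s$ci_low,
             ci_high = s$ci_high, cramers_v = s$cramers_v,
             n_obs = s$n_obs, runs_missing = s$n_missing)
}))
write_report(koos_tab, "results/table_koos_subgroups.csv")
cat("Koos subgroup performance (results/table_koos_subgroups.csv):\n")
print(koos_tab, digits = 3, row.names = FALSE)

## linear model over run x group rows
koos_grade <- as.integer(sub("koos", "", colnames(by_koos$per_run)))
group_n <- tabulate(cohort$koos, 4)
long <- data.frame(chi2 = as.vector(by_koos$per_run),
                   koos = rep(koos_grade, each = nrow(by_koos$per_run)),
                   n = rep(group_n[koos_grade],
                           each = nrow(by_koos$per_run)))
long <- long[!is.na(long$chi2), ]
fit <- glm_subgroup(long$chi2, long$koos, long$n)
cat("\nchi2 ~ tumor size + group size (per run x group):\n")
print(fit)

## (b) NI strata, complete sample
by_ni <- subgroup_evaluate(cohort, best, cfg, grouping = "ni",
                           scope = "full")
cat("\nfull-sample NI comparison:\n")
for (g in names(by_ni$groups)) {
  s <- by_ni$groups[[g]]
  cat(sprintf("  %-6s mean chi2 %.1f (CI %.1f-%.1f), V %.2f, n_obs %d\n",
              g, s$mean_chi2, s$ci_low, s$ci_high, s$cramers_v, s$n_obs))
}
print(by_ni$comparisons$no_ni_vs_ni)
ni_tab <- do.call(rbind, lapply(names(by_ni$groups), function(g) {
  s <- by_ni$groups[[g]]
  data.frame(group = g, mean_chi2 = s$mean_chi2, ci_low = s$ci_low,
             ci_high = s$ci_high, cramers_v = s$cramers_v, n_obs = s$n_obs)
}))
write_report(ni_tab, "results/table_ni_subgroups.csv")

## corrected vs uncorrected traintime within NI strata (validation scope)
unc <- get_input_sets("traintime_koos_preop")[[1]]
sub_unc <- subgroup_evaluate(cohort, unc, cfg, grouping = "ni",
                             scope = "validation")
sub_cor <- subgroup_evaluate(cohort, best, cfg, grouping = "ni",
                             scope = "validation")
cat(sprintf("\nvalidation-split non-NI stratum: corrected %.1f vs uncorrected %.1f\n",
            sub_cor$groups$no_ni$mean_chi2, sub_unc$groups$no_ni$mean_chi2))
cat(sprintf("validation-split NI stratum:     corrected %.1f vs uncorrected %.1f\n",
            sub_cor$groups$ni$mean_chi2, sub_unc$groups$ni$mean_chi2))
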