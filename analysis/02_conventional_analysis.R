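#!/usr/bin/env Rscript

## Stage 2: conventional (non-network) analysis of the simulated cohort.
##
## Spearman correlations of mean traintime (raw and cluster-corrected)
## and tumor size with postoperative and follow-up HB, overall and within
## the NI strata; the partial correlation of traintime controlling tumor
## size; and the chi-squared test of the Koos-NI association. Expects the
## cohort written by 01_simulate_cohort.R.

suppressPackageStartupMessages(library(hbnet))

cohort <- read_cohort("results/cohort.csv")

tab <- association_report(cohort)
write_report(tab, "results/table_associations.csv")
cat("association table (results/table_associations.csv):\n")
print(tab, digits = 3, row.names = FALSE)

## do larger tumors come with a separate intermediate nerve?
ind <- chi2_independence(cohort$koos, cohort$ni_separate)
cat(sprintf("\nKoos x separate-NI association: chi2 = %.2f, df = %d, p = %.4g\n",
            ind$chi2, ind$df, ind$p))

## headline contrast: traintime-outcome correlation by NI status
rho <- function(g) tab$rho[tab$group == g & tab$parameter == "mean_traintime" &
                             tab$outcome == "postop"]
cat(sprintf("postop traintime correlation: no-NI rho = %.3f vs NI rho = %.3f\n",
            rho("no_ni"), rho("ni")))
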