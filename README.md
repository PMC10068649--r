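# hbnet

Estimating postoperative facial-nerve function after vestibular schwannoma
surgery from intraoperative free-running-EMG traintime, tumor size and
preoperative function.

## The problem

During removal of a vestibular schwannoma, irritation of the facial nerve
produces pathological "A-train" discharges in the facial-muscle EMG. The
summed A-train duration per recording channel over the operation — the
*traintime* (seconds; 9 channels, 3 per nerve branch) — correlates with
the degree of postoperative facial palsy on the House-Brackmann (HB) scale
(ordinal 1–6). Two confounders limit traintime alone: a separately
coursing intermediate nerve (NI) produces abundant, often *clustered*
A-trains without corresponding deficits, and tumor size (Koos grade 1–4)
carries independent prognostic information.

`hbnet` implements, end to end and fully seeded:

* a **synthetic cohort generator** emulating a 200-patient series
  (Koos counts 18/57/70/55, 99 separate-NI patients, preoperative HB
  median 1) with the dependence structure the analysis assumes —
  outcome-independent cluster traintime that dilutes the
  traintime–outcome correlation in the NI stratum;
* the **predictor catalogue**: mean (or per-channel) traintime with
  optional cluster correction, Koos, preoperative HB, NI and cluster
  flags — 11 standard input sets;
* the **estimator**: a single-hidden-layer feed-forward network (hidden
  units = inputs, tanh/linear, two outputs: postoperative and follow-up
  HB) trained by Levenberg–Marquardt on mean squared error, with a
  multinomial logistic-regression baseline (`nnet::multinom`);
* the **evaluation engine**: repeated random 75/25 train/validation
  splits; Pearson chi-squared concordance of rounded estimates vs
  observed grades on 5×5 tables pooling both outcome time points
  (n_obs = 2 × patients); Cramér's V

  &nbsp;&nbsp;&nbsp;&nbsp;V = sqrt(χ² / (n_obs · (k − 1))), k = 5;

  bootstrap mean and 95% CI over runs; a surrogate null built by
  permuting validation features against outcomes inside each run,
  compared with a two-sample Kolmogorov–Smirnov test; Koos- and
  NI-subgroup analyses with an OLS model of subgroup performance on
  tumor and sample size;
* **conventional statistics**: Spearman and partial Spearman rank
  correlations (residual-on-ranks method), chi-squared independence
  tests, and Table-style report builders.

## Worked example

```r
library(hbnet)

cohort <- generate_cohort(cohort_params(seed = 1))   # 200 patients
cohort_summary(cohort)
#> Cohort of 200 patients
#>   Koos 1-4 counts: 18/57/70/55
#>   separate NI: 99
#>   preop HB 1-6 counts: 165/32/3/0/0/0
#>  stratum   n mean_traintime mean_cluster_traintime cluster_frequency
#>      all 200       20.52482               7.236467        0.42000000
#>    no_ni 101       14.61402               1.513589        0.07920792
#>       ni  99       26.55503              13.074959        0.76767677

best <- get_input_sets("traintime_nocluster_koos_preop")[[1]]
cfg  <- eval_config(n_runs = 200, root_seed = 1)
res  <- evaluate_with_null(cohort, best, cfg)
res$summary
#> mean chi2 71.7 (CI 66.9-76.6), Cramer's V 0.42 (large), 200 runs, n_obs 100
res$comparison
#> two-sample KS: D = 0.880, p = 0 (n = 200 vs 200)
```

Mean chi-squared 71.7 over 200 randomized splits says the rounded network
estimates and the observed postoperative/follow-up grades are strongly
concordant in held-out patients (V = 0.42, a large effect for a 5×5
table); the surrogate null centres near 14, and the KS comparison rejects
the hypothesis that performance is explained by chance pairing. On the
same cohort and seeds, Koos alone scores 0.9 and raw mean traintime alone
10.8, so the combination is doing the work; cluster-corrected traintime
beats uncorrected (71.7 vs 55.7 overall; 35.1 vs 27.2 in the validation
non-NI stratum).

The conventional analysis shows the NI dilution directly
(`association_report(cohort)`): Spearman correlation of mean traintime
with postoperative HB is 0.443 without vs 0.193 with a separate NI, and
larger tumors come with a separate NI more often (χ² = 18.1, df = 3,
p = 4e-4).

## Analysis workflow

The numbered scripts under `analysis/` run the full study on the
simulated cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort.csv + parameter sidecar
Rscript analysis/02_conventional_analysis.R  # Spearman/partial/chi-squared table
Rscript analysis/03_network_performance.R    # 11 input sets x bootstrap + null
Rscript analysis/04_subgroup_analysis.R      # Koos and NI subgroup analyses
```

Stages 3 and 4 accept an optional run count (default 200). The methods
vignette (`vignettes/estimating-facial-nerve-outcome.Rmd`) documents the
model, the generator's assumptions and every numerical choice.

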