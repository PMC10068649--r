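---
title: "Estimating facial-nerve outcome from intraoperative EMG traintime"
author: "hbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating facial-nerve outcome from intraoperative EMG traintime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbnet)
```

## The problem

During vestibular schwannoma surgery, irritation and damage of the facial
nerve show up in free-running facial-muscle EMG as "A-trains" —
high-frequency pathological discharge patterns. The summed duration of all
A-trains in a recording channel over the whole operation, the *traintime*
(seconds; 9 channels, 3 bipolar channels for each of the 3 main nerve
branches), correlates with the degree of postoperative facial palsy on the
ordinal House-Brackmann (HB) scale (1 = normal, 6 = total paralysis).

Traintime alone is an imperfect predictor. When the intermediate nerve
(NI) takes a course separate from the facial nerve, its irritation
produces abundant A-trains — often as near-simultaneous *clusters* across
most channels — without corresponding facial deficits, diluting the
traintime–outcome association. Tumor size (Koos grade 1–4) and
preoperative function carry additional information. `hbnet` implements a
pipeline that combines these sources in a small feed-forward network to
estimate postoperative and 6-month follow-up HB grades, together with the
bootstrap machinery needed to judge whether the combination actually
helps.

## The estimator

The network is a single-hidden-layer feed-forward regressor with as many
tanh hidden units as inputs and two linear outputs, the postoperative and
follow-up HB grades, trained to minimize mean squared error with a
Levenberg–Marquardt (LM) optimizer written for this package:
at each iteration the step solves
$(J^\top J + \lambda I)\,\delta = J^\top r$ for the prediction Jacobian
$J$ and residuals $r$; a step is accepted only if it reduces the error
(damping $\lambda$ divided by 10), otherwise $\lambda$ is multiplied by 10
and the step retried. Accepted steps therefore yield a non-increasing MSE
trace, which the tests assert. Training stops on relative improvement
below `convergence_tol` (default $10^{-9}$), a vanishing gradient, damping
overflow ($\lambda > 10^{12}$), or `max_iterations` (default 200).

Numerical choices:

* **Input scaling.** Predictors mix seconds (traintime can exceed 100)
  with grades (1–6) and flags (0/1); LM on such mixed scales is
  ill-conditioned. Each predictor is min–max scaled to $[-1, 1]$ using
  *training-split statistics only*, applied unchanged to validation rows,
  so no information leaks across the split. Constant training columns map
  to 0.
* **Targets** stay on the raw 1–6 grade scale so that continuous outputs
  are interpretable as grades; they are rounded to the nearest integer
  (ties half away from zero: 2.5 → 3) and clamped into 1–6.
* **Initialization** is uniform on $(-0.5, 0.5)$ from a seeded stream; no
  data-dependent initialization, so a run is a pure function of its seed.
* **No inner early-stopping split.** The 75/25 split is a
  train/validation split for *performance measurement*, not for stopping;
  consuming part of the 150 training patients for an inner validation set
  would be wasteful at this sample size. Stopping is by
  tolerance/iteration cap instead. (A toolbox default of subdividing the
  training data internally would be a different, equally defensible
  choice; this package's choice is the simpler and fully reproducible
  one.)

As a transparent baseline, the same feature sets can be fed to two
independent multinomial logistic-regression models (one per outcome time
point), fitted via `nnet::multinom`; a bivariate-continuous multinomial
model does not exist, and two independent categorical models are the
simplest faithful counterpart of "same methodology".

## Predictor sets

`standard_input_sets()` enumerates the 11 studied predictor sets: Koos
only; mean traintime only (raw and cluster-corrected); and two blocks of
four combined sets (traintime + Koos + preoperative HB, optionally adding
the separate-NI flag and/or the cluster flag, with raw or
cluster-corrected traintime). *Corrected* traintime subtracts the
A-train-cluster component per channel before averaging, so it can only
decrease. Ordinal predictors enter as integer grades (this keeps "number
of hidden units = number of inputs" meaningful; one-hot coding would
silently widen the network), flags as 0/1. By default the network receives
the mean traintime over the 9 channels; whether the original analysis fed
the mean or all 9 channels is not fully explicit, so `input_set(...,
per_channel = TRUE)` provides the 9-channel variant as a supported
alternative — both are exercised in the tests.

## The evaluation engine

A single run draws a random 75/25 split (150/50 patients at the default
cohort size), trains the estimator on the training split, rounds the
validation estimates, and computes a Pearson chi-squared statistic on the
5×5 contingency table of estimated vs observed grades over HB 1–5, pooling
the postoperative and follow-up pairs so each validation patient
contributes two observations ($n_{\mathrm{obs}} = 100$). Design choices
that matter:

* **Clamping, not dropping.** Grades above level 5 (rare) are clamped
  into level 5 rather than discarded, keeping $n_{\mathrm{obs}} = 2\times$
  patients. This is the only convention under which the reported
  chi-squared → Cramér's V pairs are internally consistent:
  $V = \sqrt{\chi^2 / (n_{\mathrm{obs}}\,(k-1))}$ with $k = 5$ maps
  54.8 → 0.37 at $n_{\mathrm{obs}} = 100$ and 164.2 → 0.46 at
  $n_{\mathrm{obs}} = 198$ (99 patients × 2), which the acceptance tests
  verify digit for digit.
* **Empty margins contribute nothing** (0/0 := 0): a table concentrated
  in one cell scores 0, and a perfect diagonal over all $k$ levels scores
  $n(k-1)$ — the theoretical maximum, attained exactly by an identity
  "oracle" estimator (`run_once(..., estimator = "oracle")`), which the
  tests use to pin the upper bound.
* **Effect-size bands** for 5×5 tables: $[0, 0.05)$ negligible,
  $[0.05, 0.13)$ small, $[0.13, 0.22)$ medium, $[0.22, 1]$ large.

`bootstrap_evaluate()` repeats the run (default 1000 times; the analysis
scripts use 200, which resolves the between-set ordering well inside the
CI widths) with per-run seeds `root_seed XOR r`, and summarizes the
distribution by its mean, a 95% CI, and the Cramér's V of the mean. The CI
is the normal-approximation CI **of the mean**
($\bar\chi^2 \pm 1.96\,s/\sqrt{n_{\mathrm{runs}}}$): the reported
intervals of the motivating analysis (e.g. 51.3 with CI 49.7–53.0 over
1000 runs) are far too narrow to be percentile ranges of the per-run
distribution, whose spread is an order of magnitude larger. A percentile
option (`ci_type = "percentile"`) is provided for the distribution itself.

**Surrogate null.** Significance is judged against a surrogate
distribution built by the identical pipeline except that, within each run,
the validation feature rows are randomly permuted relative to the outcome
rows before scoring (training is untouched). The real and surrogate
distributions are compared with a two-sample two-sided Kolmogorov–Smirnov
test (asymptotic p-value; exact only when both samples have < 30 values).
`evaluate_with_null()` trains each run's network once and scores both
pairings; because the permutation is drawn at a fixed point of the run's
seeded stream, this is bit-identical to running the two pipelines
separately with a shared root seed — an equality the tests assert — at
half the cost.

**Subgroups.** Koos subgroup concordance is computed per run on the
complete sample (the 50-patient validation split would leave tiny,
unbalanced Koos groups); NI-stratum concordance supports both the
complete-sample scope (fixed $n_{\mathrm{obs}} = 2\times$ group size) and
the validation-only scope. Runs in which a subgroup receives no scoped
patient are recorded as missing, excluded from that group's summary and
counted — silently imputing them would bias the mean chi-squared downward.
The subgroup linear model (`glm_subgroup`) is ordinary least squares of
per-run per-group chi-squared on Koos grade and group patient count with
an overall F test; the originating description ("a general linear
regression model fitted to the network estimates, taking tumor size and
sample size into account") does not fix link, response or weighting, so
this direct operationalization is a documented interpretation and its
F/t values are not treated as reproduction targets.

## Conventional statistics

`spearman_cor` is the Pearson correlation of average-rank transforms with
a two-sided t-approximation p-value ($n-2$ df); a permutation option
exists for very small samples. `partial_spearman` rank-transforms all
variables, projects the x- and y-ranks on the covariate ranks (with
intercept) and correlates the residuals — equivalent to the
inverse-correlation-matrix formula, which serves as the independent test
oracle; p uses $n-2-k$ df. Constant covariates are dropped (controlling
for a constant must reproduce the plain correlation); genuinely collinear
covariates are an error. `chi2_independence` drops empty categories with
a warning before computing $df = (r-1)(c-1)$.

## The synthetic cohort generator

The study's clinical cohort is not publicly deposited, so the pipeline is
exercised on synthetic cohorts whose *structure* — not whose numbers —
matches the study population. The generator (defaults in
`cohort_params()`) draws, per patient:

1. **Koos grade** with probabilities (18, 57, 70, 55)/200; **separate
   NI** with per-Koos probabilities (0.18, 0.46, 0.67, 0.41) — peaking at
   Koos 3 and dropping for the largest tumors, averaging 99/200;
   **preoperative HB** with probabilities (0.825, 0.16, 0.015, 0, 0, 0).
   With quota sampling (the default) these marginals are reproduced
   *exactly* by largest-remainder apportionment; i.i.d. sampling is
   available for replicate-cohort studies.
2. **Latent damage** $= 0.5\,(\mathrm{Koos}-1) + \mathcal N(0, 0.6)$: the
   within-Koos noise is what gives traintime predictive value beyond
   tumor size (setting it to 0 makes the partial traintime–outcome
   correlation controlling Koos vanish, a contrast the tests exploit).
3. **Facial traintime** per channel
   $\sim \mathrm{LogNormal}(\log 4 + 0.8\,\mathrm{damage},\ 0.8)$:
   nonnegative and right-skewed, median a few seconds to minutes.
   The distributional form and log-scale constants are free choices —
   the source material shows only box plots — made once for realism, not
   fitted to any figure.
4. **Cluster traintime**: with probability 0.75 (separate NI) or 0.15
   (no NI), every channel receives an additional
   $\mathrm{LogNormal}(\log 12,\ 0.9)$ component, *independent of damage
   and outcome*. Total traintime is facial + cluster, so the
   cluster ≤ total invariant holds by construction. This encodes the
   interpretation that clusters over-represent damage: they inflate
   traintime without carrying outcome information, which is exactly what
   dilutes the traintime–outcome correlation in the NI stratum and what
   cluster correction undoes.
5. **Outcomes**: postop
   $= \mathrm{clamp}(\mathrm{round}(1 + 0.9\max(\mathrm{damage},0) +
   (\mathrm{preop}-1) + \mathcal N(0,0.55)),\,1,\,6)$; follow-up shrinks
   postop toward preop by factor 0.6 plus $\mathcal N(0, 0.35)$ noise,
   reflecting the usual partial recovery at 6 months.

At these defaults a 2000-patient cohort shows the intended dependence
structure: the Spearman correlation of mean traintime with postoperative
HB is higher in the non-NI stratum by ≥ 0.1, clusters are about five times
more frequent with a separate NI, and Koos is positively associated with
both NI status and outcome. What the generator does **not** emulate: real
per-channel spatial correlation (channels are conditionally independent
given damage), surgeon- and era-effects, measurement error in HB grading,
and outcome grades above 5 are essentially absent. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly under a
plausible data-generating process — not that the network would achieve any
particular accuracy on clinical data. One visible consequence of the
narrow synthetic outcome scale is that single-predictor networks often
round to a single estimated grade, collapsing their concordance toward 0;
the combined-versus-single ordering is preserved, which is the property
the tests assert.

## Reproducibility

All randomness flows from explicit integer seeds: the cohort from
`cohort_params(seed=)`, each evaluation run from `root_seed XOR r` (one
stream per run covering split, initialization and permutation, in that
fixed order). Identical configurations reproduce results bit for bit;
the first analysis script verifies that a cohort regenerated from its
parameter sidecar is byte-identical.

## Problem sizes used in the shipped analyses and tests

The analysis scripts evaluate the 200-patient cohort with 200 runs per
input set; the type-I-control study uses 200 replicate null cohorts at 50
runs each; the power check uses 10 informative cohorts at 30 runs;
structural generator checks use one 2000-patient cohort. These sizes were
chosen so the full suite runs comfortably on a laptop while leaving the
Monte-Carlo error well below the margins being asserted (e.g. the
combined-vs-single chi-squared gap exceeds 40 where the CI half-width is
about 2).

## Known limitations

* The LM trainer is plain R; at these network sizes (≤ 47 weights) that
  is fast enough, but it is not meant for larger architectures.
* The surrogate-KS comparison treats the real and surrogate samples as
  independent although they share trained networks when produced by
  `evaluate_with_null()`; the type-I study shows the procedure is, if
  anything, conservative at the shipped settings.
* Follow-up dynamics are a one-parameter shrinkage; real recovery
  trajectories are richer.
* Cramér's V values printed alongside subgroup tables in the motivating
  analysis are not consistent with any single $n_{\mathrm{obs}}$
  convention for those tables; this package always reports
  $V = \sqrt{\chi^2/(n_{\mathrm{obs}}(k-1))}$ with the stated
  $n_{\mathrm{obs}}$ and leaves the discrepancy visible rather than
  matching those columns.
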