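## Bootstrap evaluation engine. One "run" draws a random 75/25
## train/validation split, trains the estimator on the training split,
## rounds the validation estimates to HB grades, and scores concordance
## between estimated and observed grades by a Pearson chi-squared
## statistic on the k x k contingency table (default k = 5, grades above
## k clamped to k), pooling the postoperative and follow-up pairs so each
## validation patient contributes two observations. Repeating the run
## many times with derived seeds yields the performance distribution; the
## surrogate null repeats the identical pipeline but permutes validation
## feature rows against the outcomes before scoring; the two
## distributions are compared with a two-sample Kolmogorov-Smirnov test.

#' Evaluation settings
#'
#' @param n_runs Number of randomized train/validation runs.
#' @param train_fraction Proportion of patients in the training split.
#' @param k_levels Number of HB levels in the concordance table (grades
#'   above `k_levels` are clamped into the top level).
#' @param alpha Significance level for the surrogate comparison.
#' @param root_seed Integer root seed; run `r` uses `root_seed XOR r`.
#' @param ci_type `"mean_normal"` for the normal-approximation CI of the
#'   mean chi-squared (mean +/- 1.96 sd/sqrt(n_runs)), or `"percentile"`
#'   for the 2.5/97.5 percentiles of the per-run distribution.
#' @return An `eval_config` object.
#' @export
eval_config <- function(n_runs = 1000L, train_fraction = 0.75,
                        k_levels = 5L, alpha = 0.05, root_seed = 1L,
                        ci_type = c("mean_normal", "percentile")) {
  stopifnot(n_runs >= 1, train_fraction > 0, train_fraction < 1,
            k_levels >= 2, k_levels <= 6, alpha > 0, alpha < 1)
  structure(list(n_runs = as.integer(n_runs),
                 train_fraction = train_fraction,
                 k_levels = as.integer(k_levels), alpha = alpha,
                 root_seed = as.integer(root_seed),
                 ci_type = match.arg(ci_type)),
            class = "eval_config")
}

#' Chi-squared concordance of estimated and observed grades
#'
#' Pearson chi-squared on the `k_levels` x `k_levels` contingency table
#' of (estimated, observed) grade pairs over levels `1..k_levels`, with
#' expected counts from the row/column marginals. Grades above `k_levels`
#' are clamped into the top level; cells with zero expected count
#' contribute nothing (0/0 := 0), so a table concentrated in a single
#' cell gives chi-squared 0 and a perfectly diagonal table over all k
#' levels gives `n * (k - 1)`.
#'
#' @param estimated,observed Equal-length integer grade vectors (1..6).
#' @param k_levels Number of table levels.
#' @return List with `chi2` and `n_obs`.
#' @export
chi2_concordance <- function(estimated, observed, k_levels = 5L) {
  if (length(estimated) != length(observed))
    stop("estimated and observed must have equal length", call. = FALSE)
  n <- length(observed)
  if (n == 0) stop("no observations", call. = FALSE)
  e <- clamp(as.integer(estimated), 1L, as.integer(k_levels))
  o <- clamp(as.integer(observed), 1L, as.integer(k_levels))
  k <- as.integer(k_levels)
  tab <- matrix(tabulate((o - 1L) * k + e, nbins = k * k), k, k)
  list(chi2 = pearson_chi2(tab), n_obs = n)
}

## Pearson chi-squared of a contingency table, 0/0 := 0 for empty margins
pearson_chi2 <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  ok <- E > 0
  sum((tab[ok] - E[ok])^2 / E[ok])
}

#' Cramér's V effect size
#'
#' `V = sqrt(chi2 / (n_obs * (k_levels - 1)))`, capped at 1. For the 5 x 5
#' concordance tables used here `k_levels - 1 = 4`.
#'
#' @param chi2 Chi-squared statistic (>= 0).
#' @param n_obs Number of observations in the table.
#' @param k_levels Number of table levels.
#' @return Effect size in \[0, 1\].
#' @export
cramers_v <- function(chi2, n_obs, k_levels = 5L) {
  stopifnot(chi2 >= 0, n_obs >= 1, k_levels >= 2)
  pmin(sqrt(chi2 / (n_obs * (k_levels - 1))), 1)
}

#' Qualitative label for a Cramér's V value
#'
#' Half-open bands for 5 x 5 tables: \[0, 0.05) negligible, \[0.05, 0.13)
#' small, \[0.13, 0.22) medium, \[0.22, 1\] large.
#'
#' @param v Effect size in \[0, 1\].
#' @return Character vector of labels.
#' @export
effect_size_label <- function(v) {
  if (any(v < 0 | v > 1)) stop("v must be in [0, 1]", call. = FALSE)
  as.character(cut(v, c(0, 0.05, 0.13, 0.22, 1 + 1e-9),
                   labels = c("negligible", "small", "medium", "large"),
                   right = FALSE, include.lowest = TRUE))
}

## One full run: split, train, score. Always computes both the real and
## the permuted (surrogate) concordance from the same trained network so
## that paired real/null evaluation costs a single training. The
## permutation is drawn at a fixed point of the run's RNG stream, so
## run_once(surrogate = TRUE/FALSE) with the same seed sees the identical
## split, initialization and permutation.
.eval_run <- function(cohort, iset, config, run_seed,
                      estimator = c("network", "lrm", "oracle"),
                      groups = NULL, group_scope = c("validation", "full")) {
  estimator <- match.arg(estimator)
  group_scope <- match.arg(group_scope)
  n <- nrow(cohort)
  if (n < 8) stop("cohort must have at least 8 patients", call. = FALSE)
  k <- config$k_levels
  Y <- cbind(cohort$postop_hb, cohort$followup_hb)
  withr::with_seed(run_seed, {
    n_train <- round(config$train_fraction * n)
    train_idx <- sample.int(n, n_train)
    val_idx <- setdiff(seq_len(n), train_idx)
    n_val <- length(val_idx)
    if (n_val < 2)
      stop("validation split has fewer than 2 patients", call. = FALSE)

    if (estimator == "oracle") {
      est_all <- Y                      # identity estimator: upper bound
      model <- NULL
    } else {
      X <- build_feature_matrix(cohort, iset)
      if (estimator == "network") {
        model <- train_network(X[train_idx, , drop = FALSE],
                               Y[train_idx, , drop = FALSE],
                               spec = network_spec(ncol(X)), scale = TRUE)
        est_all <- round_to_hb(predict_continuous(model, X))
      } else {
        sc <- scale_minmax(X[train_idx, , drop = FALSE], X)
        m_post <- train_lrm(sc$train, Y[train_idx, 1])
        m_fu <- train_lrm(sc$train, Y[train_idx, 2])
        est_all <- cbind(predict_lrm(m_post, sc$newdata),
                         predict_lrm(m_fu, sc$newdata))
        model <- list(postop = m_post, followup = m_fu)
      }
    }
    perm <- sample.int(n_val)

    est_val <- est_all[val_idx, , drop = FALSE]
    obs_val <- Y[val_idx, , drop = FALSE]
    real <- chi2_concordance(c(est_val[, 1], est_val[, 2]),
                             c(obs_val[, 1], obs_val[, 2]), k)
    est_perm <- est_val[perm, , drop = FALSE]
    surr <- chi2_concordance(c(est_perm[, 1], est_perm[, 2]),
                             c(obs_val[, 1], obs_val[, 2]), k)

    group_results <- NULL
    if (!is.null(groups)) {
      scope_idx <- if (group_scope == "full") seq_len(n) else val_idx
      group_results <- lapply(split(scope_idx, groups[scope_idx]),
                              function(gi) {
        if (length(gi) < 1) return(list(chi2 = NA_real_, n_obs = NA_integer_))
        chi2_concordance(c(est_all[gi, 1], est_all[gi, 2]),
                         c(Y[gi, 1], Y[gi, 2]), k)
      })
    }
    list(chi2 = real$chi2, chi2_surrogate = surr$chi2,
         n_obs = real$n_obs, n_val = n_val,
         train_idx = train_idx, groups = group_results)
  })
}

#' One randomized train/validation evaluation run
#'
#' @param cohort Cohort data frame.
#' @param iset An [input_set()].
#' @param config An [eval_config()].
#' @param run_seed Integer seed controlling split, weight initialization
#'   and the surrogate permutation.
#' @param surrogate If `TRUE`, score the permuted (null) pairing of
#'   validation features and outcomes instead of the real one.
#' @param estimator `"network"` (default), `"lrm"`, or `"oracle"` (an
#'   identity estimator that returns the observed grades; used to verify
#'   the perfect-concordance bound `chi2 = n_obs * (k - 1)`).
#' @return List with `chi2`, `n_obs` (2 x validation patients), `n_val`
#'   and `run_seed`.
#' @export
run_once <- function(cohort, iset, config, run_seed,
                     surrogate = FALSE,
                     estimator = c("network", "lrm", "oracle")) {
  res <- .eval_run(cohort, iset, config, run_seed, estimator = estimator)
  list(chi2 = if (surrogate) res$chi2_surrogate else res$chi2,
       n_obs = res$n_obs, n_val = res$n_val, run_seed = run_seed)
}

.summarize_runs <- function(chi2s, n_obs, config, n_missing = 0L) {
  m <- mean(chi2s)
  if (config$ci_type == "percentile") {
    ci <- stats::quantile(chi2s, c(0.025, 0.975), names = FALSE)
  } else {
    half <- 1.96 * stats::sd(chi2s) / sqrt(length(chi2s))
    if (is.na(half)) half <- 0   # single run
    ci <- c(m - half, m + half)
  }
  v <- cramers_v(m, n_obs, config$k_levels)
  structure(list(mean_chi2 = m, ci_low = ci[1], ci_high = ci[2],
                 cramers_v = v, label = effect_size_label(v),
                 n_obs = n_obs, n_runs = length(chi2s),
                 n_missing = n_missing, chi2 = chi2s),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("mean chi2 %.1f (CI %.1f-%.1f), Cramer's V %.2f (%s), %d runs, n_obs %d\n",
              x$mean_chi2, x$ci_low, x$ci_high, x$cramers_v, x$label,
              x$n_runs, x$n_obs))
  invisible(x)
}

#' Bootstrap the performance distribution over randomized runs
#'
#' Repeats [run_once()] `config$n_runs` times with derived seeds and
#' summarizes the per-run chi-squared distribution: mean, 95% CI (of the
#' mean, normal approximation, by default), and Cramér's V of the mean.
#'
#' @inheritParams run_once
#' @return A `bootstrap_summary` with the per-run chi-squared values in
#'   `$chi2`.
#' @export
bootstrap_evaluate <- function(cohort, iset, config,
                               estimator = c("network", "lrm")) {
  estimator <- match.arg(estimator)
  seeds <- derive_seeds(config$root_seed, config$n_runs)
  runs <- lapply(seeds, function(s)
    .eval_run(cohort, iset, config, s, estimator = estimator))
  .summarize_runs(vapply(runs, `[[`, numeric(1), "chi2"),
                  runs[[1]]$n_obs, config)
}

#' Surrogate (null) chi-squared distribution
#'
#' Identical pipeline to [bootstrap_evaluate()] except that in each run
#' the validation feature rows are randomly permuted relative to the
#' outcome rows before scoring, destroying any real association while
#' preserving the marginals.
#'
#' @inheritParams bootstrap_evaluate
#' @return Numeric vector of per-run chi-squared values under the null.
#' @export
surrogate_distribution <- function(cohort, iset, config,
                                   estimator = c("network", "lrm")) {
  estimator <- match.arg(estimator)
  seeds <- derive_seeds(config$root_seed, config$n_runs)
  vapply(seeds, function(s)
    .eval_run(cohort, iset, config, s,
              estimator = estimator)$chi2_surrogate, numeric(1))
}

#' Real and surrogate distributions from one set of trainings
#'
#' Trains each run's estimator once and scores it against both the true
#' and the permuted validation pairing. Bit-identical to calling
#' [bootstrap_evaluate()] and [surrogate_distribution()] with the same
#' config (the permutation is drawn at a fixed point of each run's seeded
#' stream), at half the cost.
#'
#' @inheritParams bootstrap_evaluate
#' @return List with `summary` (a `bootstrap_summary`), `surrogate` (the
#'   null chi-squared values) and `comparison` (the KS comparison of the
#'   two distributions).
#' @export
evaluate_with_null <- function(cohort, iset, config,
                               estimator = c("network", "lrm")) {
  estimator <- match.arg(estimator)
  seeds <- derive_seeds(config$root_seed, config$n_runs)
  runs <- lapply(seeds, function(s)
    .eval_run(cohort, iset, config, s, estimator = estimator))
  chi2s <- vapply(runs, `[[`, numeric(1), "chi2")
  surr <- vapply(runs, `[[`, numeric(1), "chi2_surrogate")
  summary <- .summarize_runs(chi2s, runs[[1]]$n_obs, config)
  list(summary = summary, surrogate = surr,
       comparison = compare_to_surrogate(chi2s, surr))
}

#' Compare the real distribution with its surrogate null
#'
#' Two-sample two-sided Kolmogorov-Smirnov test; the statistic is the
#' sup-distance of the two empirical CDFs. The asymptotic p-value is used
#' unless both samples have fewer than 30 values, in which case the exact
#' small-sample computation is used.
#'
#' @param real,surrogate Numeric samples (e.g. per-run chi-squared
#'   values).
#' @param exact Force exact (`TRUE`) or asymptotic (`FALSE`) p-values;
#'   `NULL` selects by sample size as above.
#' @return A `distribution_comparison` with `ks_statistic`, `p_value`,
#'   and the two samples.
#' @export
compare_to_surrogate <- function(real, surrogate, exact = NULL) {
  if (length(real) == 0 || length(surrogate) == 0)
    stop("both distributions must be non-empty", call. = FALSE)
  if (is.null(exact)) exact <- length(real) < 30 && length(surrogate) < 30
  kt <- suppressWarnings(stats::ks.test(real, surrogate,
                                        alternative = "two.sided",
                                        exact = exact))
  structure(list(ks_statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 real = real, surrogate = surrogate),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.3f, p = %.3g (n = %d vs %d)\n",
              x$ks_statistic, x$p_value, length(x$real),
              length(x$surrogate)))
  invisible(x)
}

#' Subgroup evaluation by Koos grade or NI status
#'
#' Per run, the estimator is trained on the usual random training split
#' and the concordance is then computed separately within each subgroup.
#' Grouping by Koos uses the complete sample in every run (the validation
#' split alone would leave tiny, unbalanced Koos groups); grouping by NI
#' status supports both the complete-sample scope (each patient
#' contributes two observations, so the NI / non-NI groups have fixed
#' `n_obs = 2 * group size`) and the validation-only scope. Runs in which
#' a subgroup receives no scoped patients are recorded as missing and
#' excluded from that group's summary, with the count reported.
#'
#' @inheritParams bootstrap_evaluate
#' @param grouping `"ni"` or `"koos"`.
#' @param scope `"full"` (complete sample; forced for `"koos"`) or
#'   `"validation"`.
#' @return List with `groups` (named list of `bootstrap_summary`),
#'   `per_run` (runs x groups chi-squared matrix) and `comparisons`
#'   (pairwise KS tests between group distributions).
#' @export
subgroup_evaluate <- function(cohort, iset, config,
                              grouping = c("ni", "koos"),
                              scope = c("full", "validation"),
                              estimator = c("network", "lrm")) {
  grouping <- match.arg(grouping)
  scope <- match.arg(scope)
  estimator <- match.arg(estimator)
  if (grouping == "koos") scope <- "full"
  groups <- if (grouping == "ni")
    factor(ifelse(cohort$ni_separate, "ni", "no_ni"),
           levels = c("no_ni", "ni"))
  else factor(paste0("koos", cohort$koos),
              levels = paste0("koos", sort(unique(cohort$koos))))
  if (nlevels(droplevels(groups)) < 2)
    stop("all patients fall in a single group", call. = FALSE)

  seeds <- derive_seeds(config$root_seed, config$n_runs)
  runs <- lapply(seeds, function(s)
    .eval_run(cohort, iset, config, s, estimator = estimator,
              groups = groups, group_scope = scope))

  lvls <- levels(droplevels(groups))
  chi2_mat <- sapply(lvls, function(g)
    vapply(runs, function(r)
      if (is.null(r$groups[[g]])) NA_real_ else r$groups[[g]]$chi2,
      numeric(1)))
  chi2_mat <- matrix(chi2_mat, nrow = length(runs),
                     dimnames = list(NULL, lvls))
  nobs_mat <- sapply(lvls, function(g)
    vapply(runs, function(r)
      if (is.null(r$groups[[g]])) NA_real_ else as.numeric(r$groups[[g]]$n_obs),
      numeric(1)))
  nobs_mat <- matrix(nobs_mat, nrow = length(runs),
                     dimnames = list(NULL, lvls))

  summaries <- lapply(lvls, function(g) {
    ok <- !is.na(chi2_mat[, g])
    if (!any(ok)) stop("group ", g, " never received patients",
                       call. = FALSE)
    .summarize_runs(chi2_mat[ok, g],
                    n_obs = round(mean(nobs_mat[ok, g])),
                    config, n_missing = sum(!ok))
  })
  names(summaries) <- lvls

  comparisons <- list()
  if (length(lvls) > 1) {
    for (i in seq_len(length(lvls) - 1)) for (j in seq(i + 1, length(lvls))) {
      a <- chi2_mat[!is.na(chi2_mat[, i]), i]
      b <- chi2_mat[!is.na(chi2_mat[, j]), j]
      comparisons[[paste(lvls[i], lvls[j], sep = "_vs_")]] <-
        compare_to_surrogate(a, b)
    }
  }
  list(groups = summaries, per_run = chi2_mat, comparisons = comparisons,
       grouping = grouping, scope = scope)
}
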