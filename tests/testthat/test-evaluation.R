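test_that("chi-squared concordance follows the O/E definition", {
  ## perfectly diagonal 2-level table: chi2 = n * (k_occupied - 1)
  perfect <- chi2_concordance(rep(c(1L, 2L), c(10, 10)),
                              rep(c(1L, 2L), c(10, 10)), k_levels = 2)
  expect_equal(perfect$chi2, 20)
  expect_equal(perfect$n_obs, 20)
  ## independent uniform 2x2 table
  indep <- chi2_concordance(rep(c(1L, 2L), 10),
                            rep(c(1L, 1L, 2L, 2L), 5), k_levels = 2)
  expect_equal(indep$chi2, 0)
  ## a fixed 3x3 fixture against the brute-force oracle
  est <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 1, 2, 3, 3, 3, 1)
  obs <- c(1, 2, 1, 2, 2, 3, 1, 3, 3, 1, 2, 2, 3, 1, 1)
  got <- chi2_concordance(est, obs, k_levels = 3)
  tab <- table(factor(est, 1:3), factor(obs, 1:3))
  expect_equal(got$chi2, oracle_chi2(unclass(tab)))
  ## single-cell table has chi2 0 by the 0/0 := 0 convention
  expect_equal(chi2_concordance(rep(1L, 5), rep(1L, 5))$chi2, 0)
  ## grades above k_levels are clamped into the top level
  expect_equal(chi2_concordance(c(5L, 6L), c(6L, 5L), k_levels = 5)$chi2,
               0)
  expect_error(chi2_concordance(integer(0), integer(0)), "no observations")
  expect_error(chi2_concordance(1:3, 1:4), "equal length")
})

test_that("concordance equals the oracle on random 5x5 tables", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    est <- sample(1:5, n, TRUE)
    obs <- sample(1:5, n, TRUE)
    tab <- unclass(table(factor(est, 1:5), factor(obs, 1:5)))
    expect_equal(chi2_concordance(est, obs, 5)$chi2, oracle_chi2(tab),
                 tolerance = 1e-12)
  }
})

test_that("Cramér's V transforms printed chi-squared values correctly", {
  expect_equal(round(cramers_v(54.8, 100, 5), 2), 0.37)
  expect_equal(round(cramers_v(164.2, 198, 5), 2), 0.46)
  expect_equal(cramers_v(0, 50, 5), 0)
  expect_equal(cramers_v(400, 100, 5), 1)
  expect_equal(cramers_v(1e6, 100, 5), 1)  # capped
})

test_that("V is monotone in chi2 and invariant to doubling cell counts", {
  set.seed(11)
  chi2s <- sort(runif(10, 0, 300))
  vs <- cramers_v(chi2s, 100, 5)
  expect_true(all(diff(vs) > 0))
  ## doubling all counts doubles chi2 and n, leaving V unchanged
  est <- sample(1:5, 40, TRUE); obs <- sample(1:5, 40, TRUE)
  one <- chi2_concordance(est, obs)
  two <- chi2_concordance(rep(est, 2), rep(obs, 2))
  expect_equal(two$chi2, 2 * one$chi2, tolerance = 1e-12)
  expect_equal(cramers_v(two$chi2, two$n_obs, 5),
               cramers_v(one$chi2, one$n_obs, 5), tolerance = 1e-12)
})

test_that("effect sizes are labelled by the half-open bands", {
  expect_equal(effect_size_label(c(0, 0.049, 0.05, 0.129, 0.13, 0.219,
                                   0.22, 0.36, 1)),
               c("negligible", "negligible", "small", "small", "medium",
                 "medium", "large", "large", "large"))
  expect_error(effect_size_label(1.2), "0, 1")
  expect_error(effect_size_label(-0.1), "0, 1")
})

test_that("a run splits 75/25 and pools both outcome time points", {
  co <- generate_cohort(cohort_params(seed = 13))
  iset <- get_input_sets("traintime_koos_preop")[[1]]
  cfg <- eval_config(n_runs = 1, root_seed = 1)
  r <- run_once(co, iset, cfg, run_seed = 101)
  expect_equal(r$n_val, 50)
  expect_equal(r$n_obs, 100)
  expect_gte(r$chi2, 0)
  ## same seed twice gives the identical result
  expect_identical(r, run_once(co, iset, cfg, run_seed = 101))
  expect_false(identical(r$chi2,
                         run_once(co, iset, cfg, run_seed = 102)$chi2))
})

test_that("the identity oracle attains the perfect-concordance bound", {
  co <- make_cohort(200, postop = rep(1:5, 40), followup = rep(1:5, 40))
  cfg <- eval_config(n_runs = 1, root_seed = 1)
  iset <- get_input_sets("koos_only")[[1]]
  for (seed in 1:20) {
    r <- run_once(co, iset, cfg, run_seed = seed, estimator = "oracle")
    expect_equal(r$chi2, r$n_obs * 4)
    expect_equal(cramers_v(r$chi2, r$n_obs, 5), 1)
  }
})

test_that("degenerate training splits still return a result", {
  ## constant outcomes everywhere: the network fits the constant
  co <- make_cohort(16, postop = rep(1L, 16), followup = rep(1L, 16),
                    tt = matrix(runif(16 * 9), 16, 9))
  iset <- input_set("tt", use_traintime = TRUE)
  cfg <- eval_config(n_runs = 1, root_seed = 5)
  r <- run_once(co, iset, cfg, run_seed = 3)
  expect_equal(r$n_obs, 2 * r$n_val)
  expect_equal(r$chi2, 0)  # single-cell table
})

test_that("tiny validation splits are refused", {
  co <- generate_cohort(cohort_params(n_patients = 8, seed = 2))
  iset <- get_input_sets("koos_only")[[1]]
  cfg <- eval_config(n_runs = 2, train_fraction = 0.875, root_seed = 1)
  expect_error(surrogate_distribution(co, iset, cfg), "fewer than 2")
})

test_that("bootstrap summaries are reproducible and well-formed", {
  co <- generate_cohort(cohort_params(n_patients = 60, seed = 17))
  iset <- get_input_sets("traintime_koos_preop")[[1]]
  cfg <- eval_config(n_runs = 3, root_seed = 7)
  s1 <- bootstrap_evaluate(co, iset, cfg)
  s2 <- bootstrap_evaluate(co, iset, cfg)
  expect_identical(s1, s2)
  expect_lte(s1$ci_low, s1$mean_chi2)
  expect_gte(s1$ci_high, s1$mean_chi2)
  expect_true(s1$cramers_v >= 0 && s1$cramers_v <= 1)
  expect_length(s1$chi2, 3)
})

test_that("paired real/null evaluation equals the two separate pipelines", {
  co <- generate_cohort(cohort_params(n_patients = 40, seed = 19))
  iset <- get_input_sets("traintime_koos_preop")[[1]]
  cfg <- eval_config(n_runs = 3, root_seed = 23)
  both <- evaluate_with_null(co, iset, cfg)
  expect_identical(both$summary, bootstrap_evaluate(co, iset, cfg))
  expect_identical(both$surrogate, surrogate_distribution(co, iset, cfg))
})

test_that("the surrogate null of the statistic centres near (k-1)^2", {
  ## for independent uniform grades over all 5 levels the chi-squared
  ## independence expectation is the table df = 16
  set.seed(29)
  sims <- replicate(2000, chi2_concordance(sample(1:5, 100, TRUE),
                                           sample(1:5, 100, TRUE))$chi2)
  expect_equal(mean(sims), 16, tolerance = 0.05)
})

test_that("KS comparison matches the ECDF sup-distance oracle", {
  expect_error(compare_to_surrogate(numeric(0), 1:3), "non-empty")
  same <- compare_to_surrogate(1:10, 1:10)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- compare_to_surrogate(1:10, 101:110)
  expect_equal(disjoint$ks_statistic, 1)
  set.seed(31)
  a <- rnorm(100); b <- rnorm(100, 3)
  got <- compare_to_surrogate(a, b)
  expect_equal(got$ks_statistic, oracle_ks_stat(a, b), tolerance = 1e-12)
  ## and on overlapping samples
  d <- rnorm(80, 0.5)
  expect_equal(compare_to_surrogate(a, d)$ks_statistic,
               oracle_ks_stat(a, d), tolerance = 1e-12)
})

test_that("subgroup evaluation reports one summary per group", {
  co <- generate_cohort(cohort_params(n_patients = 80, seed = 37))
  iset <- get_input_sets("traintime_koos_preop")[[1]]
  cfg <- eval_config(n_runs = 3, root_seed = 41)
  by_koos <- subgroup_evaluate(co, iset, cfg, grouping = "koos")
  expect_length(by_koos$groups, 4)
  expect_equal(by_koos$scope, "full")
  expect_named(by_koos$comparisons)
  ## single-group cohorts are refused
  co1 <- co; co1$ni_separate <- TRUE
  expect_error(subgroup_evaluate(co1, iset, cfg, grouping = "ni"),
               "single group")
})

test_that("NI-only cluster noise separates the stratum distributions", {
  ## cohort in which uncorrected traintime is informative only in the
  ## non-NI stratum: every NI patient gets large outcome-independent
  ## cluster traintime that swamps the damage signal
  p <- cohort_params(seed = 83,
                     cluster_model = list(prob_ni = 1, prob_no_ni = 0.05,
                                          log_mean = log(60),
                                          log_sd = 0.6))
  co <- generate_cohort(p)
  iset <- get_input_sets("traintime_only")[[1]]
  cfg <- eval_config(n_runs = 40, root_seed = 9)
  res <- subgroup_evaluate(co, iset, cfg, grouping = "ni", scope = "full")
  expect_gt(res$groups$no_ni$mean_chi2, res$groups$ni$mean_chi2)
  expect_lt(res$comparisons$no_ni_vs_ni$p_value, 0.01)
})

test_that("runs that empty a subgroup are excluded and counted", {
  co <- generate_cohort(cohort_params(n_patients = 40, seed = 43))
  co$ni_separate <- c(rep(TRUE, 3), rep(FALSE, 37))  # rare NI group
  iset <- get_input_sets("traintime_koos_preop")[[1]]
  cfg <- eval_config(n_runs = 20, root_seed = 47)
  res <- subgroup_evaluate(co, iset, cfg, grouping = "ni",
                           scope = "validation")
  miss <- res$groups$ni$n_missing
  expect_gte(miss, 1)
  expect_equal(res$groups$ni$n_runs, 20 - miss)
  expect_equal(sum(is.na(res$per_run[, "ni"])), miss)
  ## full-sample scope never loses a patient
  full <- subgroup_evaluate(co, iset, cfg, grouping = "ni", scope = "full")
  expect_equal(full$groups$ni$n_missing, 0)
  expect_equal(full$groups$ni$n_obs, 6)
})
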