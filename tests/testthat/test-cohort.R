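test_that("quota sampling reproduces the study marginals exactly", {
  co <- generate_cohort(cohort_params(seed = 11))
  expect_equal(unname(tabulate(co$koos, 4)), c(18, 57, 70, 55))
  expect_equal(sum(co$ni_separate), 99)
  expect_equal(unname(tabulate(co$preop_hb, 6)), c(165, 32, 3, 0, 0, 0))
  expect_equal(median(co$preop_hb), 1)
})

test_that("generation is bit-reproducible given the seed", {
  p <- cohort_params(n_patients = 60, seed = 99)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- cohort_params(n_patients = 60, seed = 100)
  expect_false(identical(generate_cohort(p), generate_cohort(p2)))
})

test_that("per-record invariants hold across seeds and sampling modes", {
  for (quota in c(TRUE, FALSE)) for (seed in 1:3) {
    co <- generate_cohort(cohort_params(n_patients = 150, quota = quota,
                                        seed = seed))
    tt <- as.matrix(co[paste0("tt_", 1:9)])
    cl <- as.matrix(co[paste0("cl_", 1:9)])
    expect_true(all(cl >= 0 & cl <= tt))
    expect_identical(co$cluster_observed, rowSums(cl) > 0)
    expect_true(all(co$koos %in% 1:4))
    expect_true(all(c(co$preop_hb, co$postop_hb, co$followup_hb) %in% 1:6))
  }
})

test_that("degenerate noise makes the outcome a function of koos and preop", {
  p <- cohort_params(n_patients = 100, seed = 5,
                     damage_model = list(baseline = 0, koos_coef = 0.5,
                                         noise_sd = 0),
                     outcome_model = list(damage_coef = 0.9, noise_sd = 0,
                                          followup_shrink = 0.6,
                                          followup_noise_sd = 0))
  co <- generate_cohort(p)
  per_cell <- tapply(co$postop_hb, interaction(co$koos, co$preop_hb),
                     function(v) length(unique(v)))
  expect_true(all(per_cell[!is.na(per_cell)] == 1))
})

test_that("invalid generator parameters are refused", {
  expect_error(cohort_params(n_patients = 5), "n_patients")
  expect_error(cohort_params(koos_probs = c(0.3, 0.3, 0.3, 0.3)),
               "summing to 1")
  expect_error(cohort_params(preop_hb_probs = rep(0.2, 6)), "summing to 1")
  expect_error(cohort_params(ni_prob_by_koos = c(0.5, 0.5, 1.2, 0.1)),
               "ni_prob_by_koos")
  expect_error(cohort_params(damage_model = list(baseline = 0,
                                                 koos_coef = 1,
                                                 noise_sd = -1)),
               "noise scales")
})

test_that("cohort_summary flags degenerate inputs and reports stratum means", {
  expect_error(cohort_summary(data.frame()), "empty")
  ident <- make_cohort(4, koos = rep(2L, 4), postop = rep(2L, 4))
  s <- cohort_summary(ident)
  expect_true(all(s$correlations$undefined))
  zero <- make_cohort(10, tt = matrix(0, 10, 9),
                      ni = rep(c(TRUE, FALSE), 5))
  sz <- cohort_summary(zero)
  expect_equal(sz$by_ni$mean_traintime, c(0, 0, 0))
})

test_that("the generator induces the assumed dependence structure", {
  co <- generate_cohort(cohort_params(n_patients = 2000, seed = 7))
  s <- cohort_summary(co)
  by_ni <- s$by_ni
  ## clusters larger and more frequent with a separate NI
  expect_gt(by_ni$mean_cluster_traintime[by_ni$stratum == "ni"],
            by_ni$mean_cluster_traintime[by_ni$stratum == "no_ni"])
  expect_gt(by_ni$cluster_frequency[by_ni$stratum == "ni"],
            by_ni$cluster_frequency[by_ni$stratum == "no_ni"])
  ## traintime-outcome correlation diluted in the NI stratum
  cor_tab <- s$correlations
  rho <- function(g) cor_tab$rho[cor_tab$stratum == g &
                                   cor_tab$parameter == "mean_traintime"]
  expect_gte(rho("no_ni") - rho("ni"), 0.1)
  ## tumor size positively associated with outcome
  expect_gt(cor_tab$rho[cor_tab$stratum == "all" &
                          cor_tab$parameter == "koos"], 0)
  ## NI probability peaks at intermediate Koos grades
  ni_rate <- tapply(co$ni_separate, co$koos, mean)
  expect_gt(ni_rate[3], ni_rate[1])
  expect_gt(ni_rate[3], ni_rate[4])
})

test_that("cohort CSV writer and reader round-trip exactly", {
  co <- generate_cohort(cohort_params(n_patients = 40, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co, ignore_attr = TRUE)
  ## a second write of the re-read cohort is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema and invariant violations are reported with rows", {
  co <- generate_cohort(cohort_params(n_patients = 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- co
  bad$cl_1[4] <- bad$tt_1[4] + 5  # cluster exceeds total
  write_cohort(bad, path)
  expect_error(read_cohort(path), "rows: 4")
  drop <- co
  drop$tt_9 <- NULL
  utils::write.csv(drop, path, row.names = FALSE)
  expect_error(read_cohort(path), "tt_9")
})
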