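## Synthetic cohort generation.
##
## No raw EMG is simulated: A-train traintime enters as per-channel summed
## durations (seconds), 9 channels per patient (3 bipolar channels per
## facial-nerve branch x 3 branches). The generative model is
##
##   damage_i   = baseline + koos_coef * (koos_i - 1) + N(0, noise_sd)
##   tt_ij      = facial_ij + cluster_ij                       (j = 1..9)
##   facial_ij  ~ LogNormal(log_mean0 + damage_coef * damage_i, log_sd)
##   cluster_ij ~ LogNormal(log_mean, log_sd) if a cluster occurs, else 0
##   P(cluster occurs) depends only on separate-NI status
##   postop_i   = clamp(round(1 + out_coef * max(damage_i, 0)
##                            + (preop_i - 1) + N(0, out_sd)), 1, 6)
##   followup_i = clamp(round(preop_i + shrink * (postop_i - preop_i)
##                            + N(0, fu_sd)), 1, 6)
##
## Cluster traintime is an additive component independent of damage and of
## outcome, larger and more frequent when a separate intermediate nerve
## (NI) is present: it over-represents damage, which is what dilutes the
## traintime-outcome correlation in the NI stratum and what cluster
## correction removes.

N_CHANNELS <- 9L

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of a 200-patient vestibular
#' schwannoma series: Koos grade counts 18/57/70/55, 99 patients with a
#' separate intermediate nerve (probability peaking at Koos 3 and dropping
#' for the largest tumors), preoperative House-Brackmann (HB) grade 1 on
#' median with range 1-3 (3 patients at HB 3), and the qualitative
#' dependence structure: traintime-outcome correlation stronger without a
#' separate NI, A-train clusters more frequent with a separate NI, Koos
#' associated with both NI status and outcome.
#'
#' @param n_patients Cohort size (>= 8).
#' @param koos_probs Probabilities of Koos grades 1-4; must sum to 1.
#' @param ni_prob_by_koos Probability of a separate intermediate nerve in
#'   each Koos stratum (each in \[0, 1\]; not a simplex).
#' @param preop_hb_probs Probabilities of preoperative HB grades 1-6; must
#'   sum to 1.
#' @param damage_model List with `baseline`, `koos_coef`, `noise_sd`
#'   (latent-damage scale; `noise_sd >= 0`).
#' @param traintime_model List with `log_mean0`, `damage_coef`, `log_sd`:
#'   per-channel facial traintime is lognormal with log-mean affine in
#'   damage (seconds).
#' @param cluster_model List with `prob_ni`, `prob_no_ni` (cluster
#'   occurrence probability by NI status) and `log_mean`, `log_sd` of the
#'   per-channel cluster traintime (seconds).
#' @param outcome_model List with `damage_coef`, `noise_sd`,
#'   `followup_shrink`, `followup_noise_sd` for the ordinal outcome map.
#' @param quota If `TRUE`, Koos, NI and preoperative-HB marginals are
#'   reproduced exactly by largest-remainder quota sampling; if `FALSE`
#'   they are sampled i.i.d.
#' @param seed Integer root seed; the whole cohort is a deterministic
#'   function of the parameters and this seed.
#' @return An object of class `cohort_params` (a validated list).
#' @export
#' @examples
#' p <- cohort_params(n_patients = 50, seed = 7)
#' cohort <- generate_cohort(p)
#' nrow(cohort)
cohort_params <- function(n_patients = 200L,
                          koos_probs = c(18, 57, 70, 55) / 200,
                          ni_prob_by_koos = c(0.18, 0.46, 0.67, 0.41),
                          preop_hb_probs = c(0.825, 0.16, 0.015, 0, 0, 0),
                          damage_model = list(baseline = 0, koos_coef = 0.5,
                                              noise_sd = 0.6),
                          traintime_model = list(log_mean0 = log(4),
                                                 damage_coef = 0.8,
                                                 log_sd = 0.8),
                          cluster_model = list(prob_ni = 0.75,
                                               prob_no_ni = 0.15,
                                               log_mean = log(12),
                                               log_sd = 0.9),
                          outcome_model = list(damage_coef = 0.9,
                                               noise_sd = 0.55,
                                               followup_shrink = 0.6,
                                               followup_noise_sd = 0.35),
                          quota = TRUE,
                          seed = 1L) {
  check_probs <- function(p, len, what) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(sprintf("%s must be %d non-negative probabilities summing to 1",
                   what, len), call. = FALSE)
  }
  if (n_patients < 8)
    stop("n_patients must be >= 8 (cannot stratify smaller cohorts)",
         call. = FALSE)
  check_probs(koos_probs, 4L, "koos_probs")
  check_probs(preop_hb_probs, 6L, "preop_hb_probs")
  if (length(ni_prob_by_koos) != 4 || any(ni_prob_by_koos < 0) ||
      any(ni_prob_by_koos > 1))
    stop("ni_prob_by_koos must be 4 probabilities in [0, 1]", call. = FALSE)
  sds <- c(damage_model$noise_sd, traintime_model$log_sd,
           cluster_model$log_sd, outcome_model$noise_sd,
           outcome_model$followup_noise_sd)
  if (any(sds < 0)) stop("noise scales must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 koos_probs = koos_probs,
                 ni_prob_by_koos = ni_prob_by_koos,
                 preop_hb_probs = preop_hb_probs,
                 damage_model = damage_model,
                 traintime_model = traintime_model,
                 cluster_model = cluster_model,
                 outcome_model = outcome_model,
                 quota = isTRUE(quota),
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' Draws one cohort from the generative model described in
#' [cohort_params()]. The result is bit-reproducible given the seed.
#'
#' @param params A `cohort_params` object.
#' @return A data frame with one row per patient: `id`, `age`, `sex`,
#'   `koos` (1-4), `preop_hb`, `postop_hb`, `followup_hb` (1-6),
#'   `ni_separate` (logical), total per-channel traintimes `tt_1..tt_9`,
#'   cluster per-channel traintimes `cl_1..cl_9` (seconds,
#'   `0 <= cl_j <= tt_j`), and `cluster_observed` (logical, `TRUE` iff the
#'   total cluster traintime is positive).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  withr::with_seed(params$seed, {
    ## tumor size and NI status (quota for exact marginals, else i.i.d.)
    if (params$quota) {
      koos <- sample(rep.int(1:4, quota_counts(n * params$koos_probs)))
    } else {
      koos <- sample(1:4, n, replace = TRUE, prob = params$koos_probs)
    }
    ni <- logical(n)
    if (params$quota) {
      n_k <- tabulate(koos, 4L)
      ni_k <- quota_counts(n_k * params$ni_prob_by_koos)
      for (k in 1:4) {
        idx <- which(koos == k)
        if (ni_k[k] > 0) ni[sample(idx, min(ni_k[k], length(idx)))] <- TRUE
      }
    } else {
      ni <- stats::runif(n) < params$ni_prob_by_koos[koos]
    }
    if (params$quota) {
      preop <- sample(rep.int(1:6, quota_counts(n * params$preop_hb_probs)))
    } else {
      preop <- sample(1:6, n, replace = TRUE, prob = params$preop_hb_probs)
    }

    age <- as.integer(clamp(round(stats::rnorm(n, 51, 14)), 21, 80))
    sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.545, 0.455))

    dm <- params$damage_model
    damage <- dm$baseline + dm$koos_coef * (koos - 1) +
      stats::rnorm(n, 0, dm$noise_sd)

    tm <- params$traintime_model
    facial <- matrix(stats::rlnorm(n * N_CHANNELS,
                                   meanlog = rep(tm$log_mean0 +
                                                   tm$damage_coef * damage,
                                                 N_CHANNELS),
                                   sdlog = tm$log_sd),
                     nrow = n, ncol = N_CHANNELS)

    cm <- params$cluster_model
    occurs <- stats::runif(n) < ifelse(ni, cm$prob_ni, cm$prob_no_ni)
    cluster <- matrix(0, nrow = n, ncol = N_CHANNELS)
    if (any(occurs)) {
      m <- sum(occurs)
      cluster[occurs, ] <- stats::rlnorm(m * N_CHANNELS,
                                         meanlog = cm$log_mean,
                                         sdlog = cm$log_sd)
    }

    om <- params$outcome_model
    postop <- as.integer(clamp(round(1 + om$damage_coef * pmax(damage, 0) +
                                       (preop - 1) +
                                       stats::rnorm(n, 0, om$noise_sd)),
                               1, 6))
    followup <- as.integer(clamp(round(preop +
                                         om$followup_shrink * (postop - preop) +
                                         stats::rnorm(n, 0,
                                                      om$followup_noise_sd)),
                                 1, 6))

    tt <- facial + cluster
    cohort <- data.frame(id = sprintf("P%04d", seq_len(n)),
                         age = age, sex = sex,
                         koos = as.integer(koos),
                         preop_hb = as.integer(preop),
                         postop_hb = postop,
                         followup_hb = followup,
                         ni_separate = ni,
                         stringsAsFactors = FALSE)
    colnames(tt) <- paste0("tt_", seq_len(N_CHANNELS))
    colnames(cluster) <- paste0("cl_", seq_len(N_CHANNELS))
    cohort <- cbind(cohort, as.data.frame(tt), as.data.frame(cluster))
    cohort$cluster_observed <- rowSums(cluster) > 0
    cohort
  })
}

#' Summarize a cohort's structure
#'
#' Reports the stratum counts and dependence summaries the evaluation
#' pipeline relies on: Koos and NI counts, mean traintime (total and
#' cluster) by NI status, cluster-observed frequency by NI status, and
#' Spearman correlations of mean traintime and Koos with postoperative HB,
#' overall and within NI strata. Correlations undefined because of zero
#' variance are returned as `NA` with `undefined = TRUE` in the
#' correlation table.
#'
#' @param cohort A cohort data frame as produced by [generate_cohort()].
#' @return A list of class `cohort_summary` with elements `n`,
#'   `koos_counts`, `ni_count`, `preop_hb_counts`, `by_ni` (per-stratum
#'   means and cluster frequency) and `correlations` (data frame).
#' @export
cohort_summary <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  mt <- rowMeans(as.matrix(cohort[paste0("tt_", seq_len(N_CHANNELS))]))
  mc <- rowMeans(as.matrix(cohort[paste0("cl_", seq_len(N_CHANNELS))]))
  strata <- list(all = rep(TRUE, nrow(cohort)),
                 no_ni = !cohort$ni_separate,
                 ni = cohort$ni_separate)
  by_ni <- do.call(rbind, lapply(names(strata), function(s) {
    i <- strata[[s]]
    data.frame(stratum = s, n = sum(i),
               mean_traintime = if (any(i)) mean(mt[i]) else NA_real_,
               mean_cluster_traintime = if (any(i)) mean(mc[i]) else NA_real_,
               cluster_frequency = if (any(i))
                 mean(cohort$cluster_observed[i]) else NA_real_)
  }))
  corr_row <- function(s, param, x, y) {
    r <- tryCatch(spearman_cor(x, y),
                  error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(stratum = s, parameter = param,
               rho = r$rho, p = r$p, undefined = is.na(r$rho))
  }
  correlations <- do.call(rbind, lapply(names(strata), function(s) {
    i <- strata[[s]]
    if (sum(i) < 4) return(NULL)
    rbind(corr_row(s, "mean_traintime", mt[i], cohort$postop_hb[i]),
          corr_row(s, "koos", cohort$koos[i], cohort$postop_hb[i]))
  }))
  structure(list(n = nrow(cohort),
                 koos_counts = tabulate(cohort$koos, 4L),
                 ni_count = sum(cohort$ni_separate),
                 preop_hb_counts = tabulate(cohort$preop_hb, 6L),
                 by_ni = by_ni,
                 correlations = correlations),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "patients\n")
  cat("  Koos 1-4 counts:", paste(x$koos_counts, collapse = "/"), "\n")
  cat("  separate NI:", x$ni_count, "\n")
  cat("  preop HB 1-6 counts:", paste(x$preop_hb_counts, collapse = "/"), "\n")
  print(x$by_ni, row.names = FALSE)
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Write a cohort to delimited text
#'
#' CSV with a header row, one patient per row, channel traintimes as
#' columns `tt_1..tt_9` and `cl_1..cl_9` (seconds, dot decimal separator),
#' booleans encoded 0/1. [read_cohort()] round-trips this format exactly.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$ni_separate <- as.integer(out$ni_separate)
  out$cluster_observed <- as.integer(out$cluster_observed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the schema (id, clinical grades, NI flag, 9 `tt_` and 9 `cl_`
#' columns, cluster flag) and the per-record invariants: grades in range,
#' `0 <= cl_j <= tt_j`, and `cluster_observed` equal to "total cluster
#' traintime > 0". Violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "koos", "preop_hb", "postop_hb",
            "followup_hb", "ni_separate",
            paste0("tt_", seq_len(N_CHANNELS)),
            paste0("cl_", seq_len(N_CHANNELS)), "cluster_observed")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("cohort file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x$ni_separate <- x$ni_separate == 1
  x$cluster_observed <- x$cluster_observed == 1
  tt <- as.matrix(x[paste0("tt_", seq_len(N_CHANNELS))])
  cl <- as.matrix(x[paste0("cl_", seq_len(N_CHANNELS))])
  bad <- which(x$koos < 1 | x$koos > 4 |
                 x$preop_hb < 1 | x$preop_hb > 6 |
                 x$postop_hb < 1 | x$postop_hb > 6 |
                 x$followup_hb < 1 | x$followup_hb > 6 |
                 rowSums(cl < 0 | cl > tt + 1e-9) > 0 |
                 x$cluster_observed != (rowSums(cl) > 0))
  if (length(bad))
    stop("invalid patient records at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  x
}
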