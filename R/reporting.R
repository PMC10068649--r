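## Report builders and pipeline configuration. The analysis scripts under
## analysis/ are thin drivers over these functions; every result table
## they write is produced here so it is unit-testable.

#' Read a pipeline configuration file
#'
#' Flat YAML with optional blocks `cohort:` (arguments to
#' [cohort_params()]), `evaluation:` (arguments to [eval_config()]) and
#' `input_sets:` (names from [standard_input_sets()]); unknown input-set
#' names are rejected with the list of valid ones. Missing blocks fall
#' back to the package defaults.
#'
#' @param path YAML file path.
#' @return List with `cohort_params`, `eval_config`, `input_sets`,
#'   `output_dir` and `verbose`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cp <- do.call(cohort_params, cfg$cohort %||% list())
  ec <- do.call(eval_config, cfg$evaluation %||% list())
  set_names <- cfg$input_sets %||% names(standard_input_sets())
  isets <- get_input_sets(unlist(set_names))
  list(cohort_params = cp, eval_config = ec, input_sets = isets,
       output_dir = cfg$output_dir %||% "results",
       verbose = isTRUE(cfg$verbose))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Network-performance report over input sets
#'
#' One row per requested input set with mean chi-squared, its 95% CI,
#' Cramér's V and the qualitative effect-size label — the layout of the
#' study's main performance table. All sets are evaluated on the same
#' derived seeds, so rows are paired comparisons.
#'
#' @param cohort Cohort data frame.
#' @param isets List of [input_set()] objects (default: the standard
#'   catalogue).
#' @param config An [eval_config()].
#' @param estimator `"network"` or `"lrm"`.
#' @return Data frame, one row per input set; the per-run chi-squared
#'   matrix is attached as attribute `"per_run"`.
#' @export
performance_report <- function(cohort, isets = standard_input_sets(),
                               config = eval_config(),
                               estimator = c("network", "lrm")) {
  estimator <- match.arg(estimator)
  summaries <- lapply(isets, function(s)
    bootstrap_evaluate(cohort, s, config, estimator = estimator))
  out <- data.frame(
    input_set = vapply(isets, `[[`, character(1), "name"),
    label = vapply(isets, `[[`, character(1), "label"),
    mean_chi2 = vapply(summaries, `[[`, numeric(1), "mean_chi2"),
    ci_low = vapply(summaries, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(summaries, `[[`, numeric(1), "ci_high"),
    cramers_v = vapply(summaries, `[[`, numeric(1), "cramers_v"),
    effect_size = vapply(summaries, `[[`, character(1), "label"),
    row.names = NULL)
  attr(out, "per_run") <- do.call(cbind, lapply(summaries, `[[`, "chi2"))
  out
}

#' Conventional association report
#'
#' Spearman correlations of mean traintime (with and without cluster
#' correction) and Koos grade with postoperative and follow-up HB, plus
#' the partial correlation of mean traintime controlling tumor size —
#' overall and within the NI strata. Two rows per parameter (postop,
#' follow-up); correlations undefined through zero variance are flagged.
#'
#' @param cohort Cohort data frame.
#' @param alpha Significance flag threshold.
#' @return Data frame with columns `group`, `parameter`, `outcome`,
#'   `rho`, `p`, `n`, `undefined`, `significant`.
#' @export
association_report <- function(cohort, alpha = 0.05) {
  mt <- rowMeans(as.matrix(cohort[paste0("tt_", seq_len(N_CHANNELS))]))
  mtc <- mt - rowMeans(as.matrix(cohort[paste0("cl_",
                                               seq_len(N_CHANNELS))]))
  outcomes <- list(postop = cohort$postop_hb, followup = cohort$followup_hb)
  strata <- list(all = rep(TRUE, nrow(cohort)),
                 no_ni = !cohort$ni_separate,
                 ni = cohort$ni_separate)
  params <- list(mean_traintime = function(i, y)
                   spearman_cor(mt[i], y[i]),
                 mean_traintime_corrected = function(i, y)
                   spearman_cor(mtc[i], y[i]),
                 koos = function(i, y)
                   spearman_cor(cohort$koos[i], y[i]),
                 mean_traintime_partial_koos = function(i, y)
                   partial_spearman(mt[i], y[i],
                                    cbind(koos = cohort$koos[i])))
  rows <- list()
  for (g in names(strata)) {
    i <- strata[[g]]
    if (sum(i) < 8) next
    for (p in names(params)) {
      ## partial correlation only reported for the whole cohort, as the
      ## stratified tables condition on NI status instead
      if (p == "mean_traintime_partial_koos" && g != "all") next
      for (o in names(outcomes)) {
        r <- params[[p]](i, outcomes[[o]])
        rows[[length(rows) + 1]] <-
          data.frame(group = g, parameter = p, outcome = o,
                     rho = r$rho, p = r$p, n = r$n,
                     undefined = isTRUE(r$undefined),
                     significant = !isTRUE(r$undefined) && !is.na(r$p) &&
                       r$p < alpha)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a result table as delimited text
#'
#' @param x Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
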