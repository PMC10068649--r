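## Predictor sets. Networks are fed, in fixed order: traintime (mean over
## the 9 channels by default, optionally the 9 per-channel values), Koos
## grade, preoperative HB grade, separate-NI flag, cluster-observed flag.
## "Corrected" traintime removes the A-train-cluster component before
## averaging. Ordinal predictors enter as integer grades; flags as 0/1.

#' Define a predictor set
#'
#' @param name Identifier (used in configs and report rows).
#' @param use_traintime Include traintime.
#' @param corrected Remove A-train-cluster traintime before averaging;
#'   only meaningful (and only allowed) when `use_traintime = TRUE`.
#' @param use_koos Include Koos tumor grade.
#' @param use_preop_hb Include preoperative HB grade.
#' @param use_ni_flag Include the separate-intermediate-nerve flag.
#' @param use_cluster_flag Include the A-train-cluster-observed flag.
#' @param per_channel If `TRUE`, feed the 9 per-channel traintimes instead
#'   of their mean.
#' @param label Human-readable row label for reports; defaults to `name`.
#' @return An `input_set` object.
#' @export
input_set <- function(name,
                      use_traintime = FALSE, corrected = FALSE,
                      use_koos = FALSE, use_preop_hb = FALSE,
                      use_ni_flag = FALSE, use_cluster_flag = FALSE,
                      per_channel = FALSE, label = name) {
  if (!any(use_traintime, use_koos, use_preop_hb, use_ni_flag,
           use_cluster_flag))
    stop("input set must enable at least one predictor", call. = FALSE)
  if (corrected && !use_traintime)
    stop("corrected = TRUE requires use_traintime = TRUE", call. = FALSE)
  if (per_channel && !use_traintime)
    stop("per_channel = TRUE requires use_traintime = TRUE", call. = FALSE)
  structure(list(name = name, use_traintime = use_traintime,
                 corrected = corrected, use_koos = use_koos,
                 use_preop_hb = use_preop_hb, use_ni_flag = use_ni_flag,
                 use_cluster_flag = use_cluster_flag,
                 per_channel = per_channel, label = label),
            class = "input_set")
}

#' Mean traintime of one patient record
#'
#' Arithmetic mean over the 9 channels of the summed A-train durations;
#' with `corrected = TRUE` the per-channel cluster traintime is subtracted
#' first, so the corrected mean never exceeds the uncorrected one.
#'
#' @param record One-row cohort data frame (or a list with `tt_1..tt_9`,
#'   `cl_1..cl_9`).
#' @param corrected Remove the cluster component.
#' @return Mean traintime in seconds (>= 0).
#' @export
mean_traintime <- function(record, corrected = FALSE) {
  tt <- as.numeric(record[paste0("tt_", seq_len(N_CHANNELS))])
  if (corrected)
    tt <- tt - as.numeric(record[paste0("cl_", seq_len(N_CHANNELS))])
  if (any(tt < -1e-9))
    stop("cluster traintime exceeds total traintime", call. = FALSE)
  mean(pmax(tt, 0))
}

#' Build one patient's feature vector
#'
#' Predictors appear in the fixed order traintime, Koos, preop HB, NI
#' flag, cluster flag; disabled predictors are absent. Flags are encoded
#' 0/1, ordinal grades as integers.
#'
#' @param record One-row cohort data frame.
#' @param spec An [input_set()].
#' @return Named numeric vector.
#' @export
build_features <- function(record, spec) {
  stopifnot(inherits(spec, "input_set"))
  v <- c()
  if (spec$use_traintime) {
    if (spec$per_channel) {
      tt <- as.numeric(record[paste0("tt_", seq_len(N_CHANNELS))])
      if (spec$corrected)
        tt <- pmax(tt - as.numeric(record[paste0("cl_",
                                                 seq_len(N_CHANNELS))]), 0)
      names(tt) <- paste0("traintime_ch", seq_len(N_CHANNELS))
      v <- c(v, tt)
    } else {
      v <- c(v, traintime = mean_traintime(record, spec$corrected))
    }
  }
  if (spec$use_koos) v <- c(v, koos = as.numeric(record[["koos"]]))
  if (spec$use_preop_hb)
    v <- c(v, preop_hb = as.numeric(record[["preop_hb"]]))
  if (spec$use_ni_flag)
    v <- c(v, ni_flag = as.numeric(record[["ni_separate"]]))
  if (spec$use_cluster_flag)
    v <- c(v, cluster_flag = as.numeric(record[["cluster_observed"]]))
  if (any(!is.finite(v))) stop("non-finite feature value", call. = FALSE)
  v
}

#' Feature matrix for a whole cohort
#'
#' Vectorized equivalent of applying [build_features()] row by row.
#'
#' @param cohort Cohort data frame.
#' @param spec An [input_set()].
#' @return Numeric matrix, one row per patient, columns in the fixed
#'   predictor order.
#' @export
build_feature_matrix <- function(cohort, spec) {
  stopifnot(inherits(spec, "input_set"))
  cols <- list()
  if (spec$use_traintime) {
    tt <- as.matrix(cohort[paste0("tt_", seq_len(N_CHANNELS))])
    if (spec$corrected)
      tt <- pmax(tt - as.matrix(cohort[paste0("cl_",
                                              seq_len(N_CHANNELS))]), 0)
    if (spec$per_channel) {
      colnames(tt) <- paste0("traintime_ch", seq_len(N_CHANNELS))
      cols$traintime <- tt
    } else {
      cols$traintime <- matrix(rowMeans(tt), ncol = 1,
                               dimnames = list(NULL, "traintime"))
    }
  }
  add_col <- function(x, nm) matrix(as.numeric(x), ncol = 1,
                                    dimnames = list(NULL, nm))
  if (spec$use_koos) cols$koos <- add_col(cohort$koos, "koos")
  if (spec$use_preop_hb)
    cols$preop_hb <- add_col(cohort$preop_hb, "preop_hb")
  if (spec$use_ni_flag)
    cols$ni_flag <- add_col(cohort$ni_separate, "ni_flag")
  if (spec$use_cluster_flag)
    cols$cluster_flag <- add_col(cohort$cluster_observed, "cluster_flag")
  do.call(cbind, unname(cols))
}

#' The standard catalogue of predictor sets
#'
#' The two single-predictor sets (Koos only; mean traintime only, with and
#' without cluster correction) and the two blocks of four combined sets
#' (traintime + Koos + preop HB, optionally adding the NI flag and/or the
#' cluster flag, with uncorrected and cluster-corrected traintime): 11
#' sets in total.
#'
#' @return Named list of [input_set()] objects.
#' @export
standard_input_sets <- function() {
  combined <- function(prefix, label0, corrected) {
    sets <- list(
      input_set(prefix, use_traintime = TRUE, corrected = corrected,
                use_koos = TRUE, use_preop_hb = TRUE, label = label0),
      input_set(paste0(prefix, "_ni"), use_traintime = TRUE,
                corrected = corrected, use_koos = TRUE, use_preop_hb = TRUE,
                use_ni_flag = TRUE, label = paste0(label0, " + sep. intermedius")),
      input_set(paste0(prefix, "_cluster"), use_traintime = TRUE,
                corrected = corrected, use_koos = TRUE, use_preop_hb = TRUE,
                use_cluster_flag = TRUE,
                label = paste0(label0, " + A-train cluster")),
      input_set(paste0(prefix, "_ni_cluster"), use_traintime = TRUE,
                corrected = corrected, use_koos = TRUE, use_preop_hb = TRUE,
                use_ni_flag = TRUE, use_cluster_flag = TRUE,
                label = paste0(label0, " + sep. intermedius and A-train cluster")))
    names(sets) <- c(prefix, paste0(prefix, c("_ni", "_cluster",
                                              "_ni_cluster")))
    sets
  }
  sets <- c(list(koos_only = input_set("koos_only", use_koos = TRUE,
                                       label = "Koos only"),
                 traintime_only = input_set("traintime_only",
                                            use_traintime = TRUE,
                                            label = "Mean traintime only"),
                 traintime_nocluster_only =
                   input_set("traintime_nocluster_only",
                             use_traintime = TRUE, corrected = TRUE,
                             label = "Mean traintime only (without clusters)")),
            combined("traintime_koos_preop",
                     "Traintime, Koos, preOP HB", corrected = FALSE),
            combined("traintime_nocluster_koos_preop",
                     "Traintime (without clusters), Koos, preOP HB",
                     corrected = TRUE))
  sets
}

#' Look up input sets by name
#'
#' @param names Character vector of catalogue names.
#' @return List of `input_set` objects.
#' @export
get_input_sets <- function(names) {
  catalogue <- standard_input_sets()
  unknown <- setdiff(names, names(catalogue))
  if (length(unknown))
    stop("unknown input set(s): ", paste(unknown, collapse = ", "),
         "\nvalid names: ", paste(names(catalogue), collapse = ", "),
         call. = FALSE)
  catalogue[names]
}

#' Min-max scale features to \[-1, 1\] using training statistics
#'
#' Column ranges are taken from the training rows only and applied to both
#' splits, avoiding leakage; constant training columns map to 0.
#'
#' @param train,newdata Numeric matrices with identical columns.
#' @return List with scaled `train`, `newdata`, and the `lo`/`hi` ranges.
#' @keywords internal
scale_minmax <- function(train, newdata = NULL) {
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant column -> centered at 0
  sc <- function(m) sweep(sweep(m, 2, (lo + hi) / 2), 2, span / 2, "/")
  list(train = sc(train),
       newdata = if (!is.null(newdata)) sc(newdata),
       lo = lo, hi = hi)
}
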