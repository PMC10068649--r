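## Multinomial logistic-regression baseline. Each outcome time point
## (postop, follow-up) gets its own multinomial model over the observed
## grade categories, fitted by nnet::multinom. Degenerate single-category
## targets yield a constant predictor rather than an error, so the
## bootstrap engine never crashes on an unlucky training split.

#' Fit the multinomial logistic-regression baseline
#'
#' @param features Numeric matrix of predictors (rows = patients).
#' @param targets Integer HB grades in 1..6 for one outcome time point.
#' @param maxit Maximum optimizer iterations (bounds the fit under
#'   complete separation, which is reported as a warning).
#' @return An `lrm_model` with the coefficient matrix over grade
#'   categories (reference = lowest observed grade), the observed levels
#'   and the fitted log-likelihood.
#' @export
train_lrm <- function(features, targets, maxit = 200L) {
  X <- as.matrix(features)
  y <- as.integer(targets)
  if (any(y < 1 | y > 6)) stop("targets must be HB grades 1..6",
                               call. = FALSE)
  levels_obs <- sort(unique(y))
  if (length(levels_obs) < 2) {
    return(structure(list(levels = levels_obs, coefficients = NULL,
                          log_lik = 0, degenerate = TRUE),
                     class = "lrm_model"))
  }
  yf <- factor(y, levels = levels_obs)
  df <- data.frame(X)
  colnames(df) <- paste0("x", seq_len(ncol(X)))
  df$.y <- yf
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = maxit)
  coefs <- stats::coef(fit)
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1,
                                           dimnames = list(
                                             as.character(levels_obs[2]),
                                             names(coefs)))
  structure(list(levels = levels_obs, coefficients = coefs,
                 log_lik = as.numeric(stats::logLik(fit)),
                 n_features = ncol(X), degenerate = FALSE),
            class = "lrm_model")
}

#' Category probabilities from an `lrm_model`
#' @keywords internal
lrm_probs <- function(model, X) {
  if (model$degenerate) {
    pr <- matrix(1, nrow(X), 1)
    colnames(pr) <- as.character(model$levels)
    return(pr)
  }
  eta <- as.matrix(X) %*% t(model$coefficients[, -1, drop = FALSE])
  eta <- sweep(eta, 2, model$coefficients[, 1], "+")
  eta <- cbind(0, eta)           # reference category first
  eta <- eta - apply(eta, 1, max)
  pr <- exp(eta)
  pr <- pr / rowSums(pr)
  colnames(pr) <- as.character(model$levels)
  pr
}

#' Predict HB grades from the logistic-regression baseline
#'
#' Argmax of the category probabilities; exact ties break toward the
#' lower grade.
#'
#' @param model An `lrm_model`.
#' @param features Numeric vector or matrix of predictors.
#' @return Integer grades in 1..6.
#' @export
predict_lrm <- function(model, features) {
  stopifnot(inherits(model, "lrm_model"))
  single <- is.null(dim(features))
  X <- if (single) matrix(features, nrow = 1) else as.matrix(features)
  if (!model$degenerate && ncol(X) != model$n_features)
    stop("feature length does not match the fitted model", call. = FALSE)
  pr <- lrm_probs(model, X)
  idx <- apply(pr, 1, which.max)   # first max = lowest grade on ties
  out <- model$levels[idx]
  if (single) out[1] else out
}
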