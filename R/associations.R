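## Conventional association statistics: Spearman and partial Spearman
## rank correlations (p by t-approximation, with a permutation option for
## very small samples), Pearson chi-squared test of independence, and the
## ordinary-least-squares subgroup model relating per-run per-Koos
## chi-squared values to tumor size and group sample size.

#' Spearman rank correlation
#'
#' Pearson correlation of the average-rank transforms (ties receive
#' average ranks); two-sided p-value from the t-approximation with
#' `n - 2` degrees of freedom, or from a permutation test when
#' `method = "permutation"` (recommended only for n < 20).
#'
#' @param x,y Equal-length numeric vectors (n >= 4).
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for the permutation p-value.
#' @return A `correlation_result`: list with `rho`, `p`, `n`,
#'   `covariates` (empty) and `undefined` (`TRUE` when either input has
#'   zero variance, in which case `rho` and `p` are `NA`).
#' @export
spearman_cor <- function(x, y, method = c("t", "permutation"),
                         n_perm = 2000L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          covariates = character(0), undefined = TRUE),
                     class = "correlation_result"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (method == "t") .t_pvalue(rho, df = n - 2) else {
    obs <- abs(rho)
    perm <- vapply(seq_len(n_perm), function(i)
      abs(stats::cor(rx, sample(ry))), numeric(1))
    (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  }
  structure(list(rho = rho, p = p, n = n, covariates = character(0),
                 undefined = FALSE),
            class = "correlation_result")
}

.t_pvalue <- function(r, df) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("correlation undefined (zero variance), n =", x$n, "\n")
  } else {
    cat(sprintf("rho = %.3f, p = %.4g, n = %d%s\n", x$rho, x$p, x$n,
                if (length(x$covariates))
                  paste0(" | controlling: ",
                         paste(x$covariates, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Partial Spearman rank correlation
#'
#' All variables are rank-transformed (average ranks); `x` and `y` ranks
#' are each regressed on the covariate ranks (with intercept) by least
#' squares, and the partial correlation is the Pearson correlation of the
#' two residual vectors — equivalent to the inverse-correlation-matrix
#' formula. Two-sided p from the t-approximation with `n - 2 - k` degrees
#' of freedom (k = number of non-constant covariates). Constant
#' covariates carry no information and are dropped, so controlling for a
#' constant reproduces the plain Spearman correlation; mutually collinear
#' covariates are an error.
#'
#' @param x,y Equal-length numeric vectors.
#' @param covariates Numeric vector, matrix or data frame of control
#'   variables (may be empty, giving plain [spearman_cor()]).
#' @return A `correlation_result` with the covariate names recorded.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      length(covariates) == 0)
    return(spearman_cor(x, y))
  Z <- as.matrix(covariates)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  if (length(x) != length(y) || nrow(Z) != length(x))
    stop("length mismatch", call. = FALSE)
  keep <- apply(Z, 2, function(z) stats::var(z) > 0)
  Z <- Z[, keep, drop = FALSE]
  k <- ncol(Z)
  n <- length(x)
  if (k == 0) return(spearman_cor(x, y))
  if (n <= k + 3)
    stop("need n > number of covariates + 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          covariates = colnames(Z), undefined = TRUE),
                     class = "correlation_result"))
  RZ <- apply(Z, 2, rank)
  D <- cbind(1, RZ)
  if (qr(D)$rank < ncol(D))
    stop("collinear covariates", call. = FALSE)
  res_x <- stats::lm.fit(D, rank(x))$residuals
  res_y <- stats::lm.fit(D, rank(y))$residuals
  rho <- stats::cor(res_x, res_y)
  structure(list(rho = rho, p = .t_pvalue(rho, df = n - 2 - k), n = n,
                 covariates = colnames(Z), undefined = FALSE),
            class = "correlation_result")
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared on the r x c contingency table of two categorical
#' sequences, `df = (r - 1)(c - 1)`, p from the chi-squared distribution.
#' Categories with a zero marginal are dropped with a warning before the
#' degrees of freedom are computed.
#'
#' @param a,b Equal-length categorical (or discrete) sequences.
#' @return List with `chi2`, `df`, `p`, and the contingency `table`.
#' @export
chi2_independence <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tab <- table(a, b)
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("dropping empty categories before computing df")
    tab <- tab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 categories in each sequence", call. = FALSE)
  chi2 <- pearson_chi2(unclass(tab))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = tab)
}

#' Linear model of subgroup performance on tumor and sample size
#'
#' Ordinary least squares of per-run per-Koos-group chi-squared values on
#' the Koos grade and the group's patient count (with intercept),
#' reporting the overall F statistic and per-coefficient t tests. Used to
#' ask whether subgroup performance differences persist after accounting
#' for the different group sizes.
#'
#' @param estimates Numeric response: one chi-squared value per
#'   run-by-group row.
#' @param koos Koos grade of each row's group.
#' @param group_n Patient count of each row's group.
#' @return A `glm_fit`: coefficient table (estimate, SE, t, p), overall
#'   `f_statistic` with `f_p` (flagged `NA` for a constant response), and
#'   the underlying `lm` fit.
#' @export
glm_subgroup <- function(estimates, koos, group_n) {
  if (length(unique(koos)) < 2)
    stop("need at least 2 Koos levels", call. = FALSE)
  df <- data.frame(chi2 = estimates, koos = as.numeric(koos),
                   n = as.numeric(group_n))
  X <- cbind(1, df$koos, df$n)
  rk <- qr(X)$rank
  if (rk < 3) {
    cols <- c("(intercept)", "koos", "group_n")
    stop("rank-deficient design; collinear columns among: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(chi2 ~ koos + n, data = df)
  sm <- summary(fit)
  coefs <- sm$coefficients
  rownames(coefs) <- c("(intercept)", "tumor_size", "group_n")
  fstat <- sm$fstatistic
  constant_response <- stats::var(df$chi2) == 0
  structure(list(coefficients = coefs,
                 f_statistic = if (constant_response) NA_real_ else
                   unname(fstat[1]),
                 f_p = if (constant_response) NA_real_ else
                   unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)),
                 constant_response = constant_response,
                 fit = fit),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  print(round(x$coefficients, 4))
  if (x$constant_response) cat("constant response: F undefined\n")
  else cat(sprintf("F = %.1f, p = %.3g\n", x$f_statistic, x$f_p))
  invisible(x)
}
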