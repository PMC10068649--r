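## Single-hidden-layer feed-forward regressor with two continuous outputs
## (postoperative and follow-up HB grade), trained by Levenberg-Marquardt
## on mean squared error. The hidden layer has as many tanh units as there
## are inputs; outputs are linear. Inputs are min-max scaled to [-1, 1]
## with training-split statistics; targets stay on the raw 1-6 grade
## scale so outputs are interpretable as grades before rounding.
##
## Forward pass: H = tanh(X W1 + b1),  Yhat = H W2 + b2.
## LM step: solve (J'J + lambda I) d = J'r for the prediction Jacobian J
## and residuals r = y - yhat; accept if the SSE decreases (damping down),
## otherwise increase damping and retry. Accepted steps therefore give a
## non-increasing MSE trace.

#' Network architecture and training settings
#'
#' @param n_inputs Number of input features.
#' @param n_hidden Hidden units; fixed equal to `n_inputs`.
#' @param max_iterations Maximum accepted LM iterations.
#' @param damping_init,damping_up,damping_down Initial LM damping and its
#'   multiplicative update factors (all positive).
#' @param convergence_tol Relative SSE-improvement / step-size tolerance.
#' @param init_seed Integer seed for the weight initialization, or `NULL`
#'   to draw from the caller's RNG stream.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_inputs, n_hidden = n_inputs,
                         max_iterations = 200L,
                         damping_init = 1e-2, damping_up = 10,
                         damping_down = 0.1, convergence_tol = 1e-9,
                         init_seed = NULL) {
  if (n_hidden != n_inputs)
    stop("n_hidden must equal n_inputs", call. = FALSE)
  stopifnot(n_inputs >= 1, max_iterations >= 1, damping_init > 0,
            damping_up > 1, damping_down > 0, damping_down < 1,
            convergence_tol > 0)
  structure(list(n_inputs = as.integer(n_inputs),
                 n_hidden = as.integer(n_hidden), n_outputs = 2L,
                 max_iterations = as.integer(max_iterations),
                 damping_init = damping_init, damping_up = damping_up,
                 damping_down = damping_down,
                 convergence_tol = convergence_tol,
                 init_seed = init_seed),
            class = "network_spec")
}

## weight vector <-> parameter matrices
.unpack_weights <- function(w, p, h, q) {
  i <- 0
  W1 <- matrix(w[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(h * q)], h, q); i <- i + h * q
  b2 <- w[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.forward <- function(par, X) {
  n <- nrow(X)
  H <- tanh(X %*% par$W1 + rep(par$b1, each = n))
  Yhat <- H %*% par$W2 + rep(par$b2, each = n)
  list(H = H, Yhat = Yhat)
}

## Jacobian of vec(Yhat) (column-major over outputs) w.r.t. the weight
## vector; rows ordered as (observation, output) pairs, outputs stacked.
.jacobian <- function(par, X, H) {
  n <- nrow(X); p <- ncol(X); h <- ncol(H); q <- ncol(par$W2)
  dH <- 1 - H * H
  nw <- p * h + h + h * q + q
  J <- matrix(0, n * q, nw)
  for (o in seq_len(q)) {
    rows <- (o - 1) * n + seq_len(n)
    ## hidden-layer weights: dyhat_o/dW1[j,k] = W2[k,o] * dH[,k] * X[,j]
    G <- dH * rep(par$W2[, o], each = n)  # n x h
    for (k in seq_len(h)) {
      J[rows, (k - 1) * p + seq_len(p)] <- X * G[, k]
    }
    J[rows, p * h + seq_len(h)] <- G
    J[rows, p * h + h + (o - 1) * h + seq_len(h)] <- H
    J[rows, p * h + h + h * q + o] <- 1
  }
  J
}

#' Train the feed-forward network by Levenberg-Marquardt
#'
#' @param features Numeric matrix (rows = patients) or list of equal-length
#'   feature vectors.
#' @param targets Two-column matrix of (postop, follow-up) HB grades in
#'   1..6.
#' @param spec A [network_spec()]; defaults to the architecture implied by
#'   `features` (hidden units = inputs).
#' @param scale Min-max scale inputs to \[-1, 1\] with statistics of
#'   `features` (stored in the model and applied at prediction time).
#' @return A `network_model` with weight matrices, the input scaling, and
#'   `loss_trace` (MSE at initialization and after each accepted step;
#'   non-increasing by construction).
#' @export
train_network <- function(features, targets, spec = NULL, scale = TRUE) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  X <- as.matrix(features)
  Y <- as.matrix(targets)
  if (ncol(Y) != 2) stop("targets must have two columns", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("row mismatch", call. = FALSE)
  if (nrow(unique(X)) < 2)
    warning("fewer than 2 distinct training rows; fit is a constant")
  if (is.null(spec)) spec <- network_spec(ncol(X))
  if (ncol(X) != spec$n_inputs)
    stop("feature dimension does not match spec$n_inputs", call. = FALSE)

  scaling <- NULL
  if (scale) {
    sc <- scale_minmax(X)
    X <- sc$train
    scaling <- list(lo = sc$lo, hi = sc$hi)
  }

  p <- spec$n_inputs; h <- spec$n_hidden; q <- spec$n_outputs
  nw <- p * h + h + h * q + q
  draw_init <- function() stats::runif(nw, -0.5, 0.5)
  w <- if (is.null(spec$init_seed)) draw_init() else
    withr::with_seed(spec$init_seed, draw_init())

  n <- nrow(X)
  par <- .unpack_weights(w, p, h, q)
  fw <- .forward(par, X)
  r <- as.vector(Y - fw$Yhat)
  sse <- sum(r * r)
  trace <- sse / (n * q)
  lambda <- spec$damping_init
  tol <- spec$convergence_tol
  status <- "max_iterations"

  for (iter in seq_len(spec$max_iterations)) {
    J <- .jacobian(par, X, fw$H)
    g <- crossprod(J, r)                 # gradient of 0.5*SSE
    if (max(abs(g)) < 1e-10 * (1 + sse)) { status <- "gradient"; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (lambda <= 1e12) {
      step <- tryCatch(solve(JtJ + diag(lambda, nw), g),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        w_new <- w + as.vector(step)
        par_new <- .unpack_weights(w_new, p, h, q)
        fw_new <- .forward(par_new, X)
        r_new <- as.vector(Y - fw_new$Yhat)
        sse_new <- sum(r_new * r_new)
        if (is.finite(sse_new) && sse_new < sse) {
          improv <- (sse - sse_new) / max(sse, .Machine$double.eps)
          small_step <- sqrt(sum(step^2)) < tol * (1 + sqrt(sum(w^2)))
          w <- w_new; par <- par_new; fw <- fw_new; r <- r_new
          sse <- sse_new
          trace <- c(trace, sse / (n * q))
          lambda <- max(lambda * spec$damping_down, 1e-12)
          accepted <- TRUE
          if (improv < tol || small_step) status <- "converged"
          break
        }
      }
      lambda <- lambda * spec$damping_up
    }
    if (!accepted) { status <- "damping_overflow"; break }
    if (status == "converged") break
  }
  if (!all(is.finite(w)))
    stop("network training diverged (non-finite weights)", call. = FALSE)

  structure(list(W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
                 spec = spec, scaling = scaling, loss_trace = trace,
                 status = status),
            class = "network_model")
}

#' Continuous network outputs for new patients
#'
#' @param model A `network_model`.
#' @param features Numeric vector (one patient) or matrix (one row each).
#' @return For a vector input, a named length-2 vector
#'   `(postop_estimate, followup_estimate)`; for a matrix, an n-by-2
#'   matrix.
#' @export
predict_continuous <- function(model, features) {
  stopifnot(inherits(model, "network_model"))
  single <- is.null(dim(features))
  X <- if (single) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(X) != model$spec$n_inputs)
    stop("feature length does not match the model's n_inputs", call. = FALSE)
  if (!is.null(model$scaling)) {
    lo <- model$scaling$lo; hi <- model$scaling$hi
    span <- hi - lo; span[span == 0] <- 1
    X <- sweep(sweep(X, 2, (lo + hi) / 2), 2, span / 2, "/")
  }
  Yhat <- .forward(list(W1 = model$W1, b1 = model$b1,
                        W2 = model$W2, b2 = model$b2), X)$Yhat
  colnames(Yhat) <- c("postop_estimate", "followup_estimate")
  if (single) Yhat[1, ] else Yhat
}

#' @export
predict.network_model <- function(object, newdata, ...) {
  predict_continuous(object, newdata)
}

#' Round a continuous estimate to an HB grade
#'
#' Nearest integer, ties rounded half away from zero, clamped into 1..6
#' (so 2.5 becomes 3, 0.3 becomes 1, 7.2 becomes 6).
#'
#' @param estimate Numeric vector of continuous grade estimates.
#' @return Integer grades in 1..6 (same shape as the input).
#' @export
round_to_hb <- function(estimate) {
  if (any(!is.finite(estimate)))
    stop("non-finite grade estimate", call. = FALSE)
  rounded <- sign(estimate) * floor(abs(estimate) + 0.5)
  out <- clamp(rounded, 1, 6)
  if (is.matrix(estimate))
    matrix(as.integer(out), nrow(estimate), ncol(estimate),
           dimnames = dimnames(estimate))
  else as.integer(out)
}

#' Serialize a network model to a versioned text format
#'
#' Plain key-value/array text so trained models can be audited and
#' reloaded without binary files.
#'
#' @param model A `network_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_model <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c("hbnet_network_model v1",
             sprintf("n_inputs %d", model$spec$n_inputs),
             sprintf("n_hidden %d", model$spec$n_hidden),
             paste("W1", num(model$W1)), paste("b1", num(model$b1)),
             paste("W2", num(model$W2)), paste("b2", num(model$b2)),
             paste("scaling_lo", if (is.null(model$scaling)) "none" else
               num(model$scaling$lo)),
             paste("scaling_hi", if (is.null(model$scaling)) "none" else
               num(model$scaling$hi)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model written by [write_network_model()]
#'
#' @param path File path.
#' @return A `network_model` (loss trace not preserved).
#' @export
read_network_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "hbnet_network_model v1"))
    stop("unrecognized model file format", call. = FALSE)
  field <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))][1]
    strsplit(sub(paste0("^", key, " "), "", ln), " ")[[1]]
  }
  p <- as.integer(field("n_inputs")[1])
  h <- as.integer(field("n_hidden")[1])
  lo <- field("scaling_lo"); hi <- field("scaling_hi")
  structure(list(W1 = matrix(as.numeric(field("W1")), p, h),
                 b1 = as.numeric(field("b1")),
                 W2 = matrix(as.numeric(field("W2")), h, 2),
                 b2 = as.numeric(field("b2")),
                 spec = network_spec(p, h),
                 scaling = if (identical(lo, "none")) NULL else
                   list(lo = as.numeric(lo), hi = as.numeric(hi)),
                 loss_trace = numeric(0), status = "loaded"),
            class = "network_model")
}
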