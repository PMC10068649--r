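## Independent brute-force oracles used to check the package's statistics.
## These deliberately re-derive each quantity from its definition rather
## than calling the implementation under test.

## Pearson chi-squared by explicit O/E summation over all cells
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      if (e > 0) total <- total + (tab[i, j] - e)^2 / e
    }
  }
  total
}

## two-sample KS statistic as the sup-distance of the empirical CDFs,
## evaluated over the pooled sample points
oracle_ks_stat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

## Spearman rho as Pearson correlation of average ranks, from scratch
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## partial correlation of ranked variables via the inverse of the
## correlation matrix: r_xy.z = -S[1,2] / sqrt(S[1,1] * S[2,2])
oracle_partial_spearman <- function(x, y, Z) {
  M <- cbind(rank(x), rank(y), apply(as.matrix(Z), 2, rank))
  S <- solve(stats::cor(M))
  -S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

## a small cohort data frame built directly (not via the generator), with
## controllable traintime and outcomes
make_cohort <- function(n, koos = rep(1:4, length.out = n),
                        preop = rep(1L, n),
                        postop = rep(1L, n), followup = postop,
                        ni = rep(FALSE, n),
                        tt = matrix(1, n, 9), cl = matrix(0, n, 9)) {
  co <- data.frame(id = sprintf("P%04d", seq_len(n)),
                   age = rep(50L, n), sex = rep("F", n),
                   koos = as.integer(koos), preop_hb = as.integer(preop),
                   postop_hb = as.integer(postop),
                   followup_hb = as.integer(followup),
                   ni_separate = ni, stringsAsFactors = FALSE)
  colnames(tt) <- paste0("tt_", 1:9)
  colnames(cl) <- paste0("cl_", 1:9)
  co <- cbind(co, as.data.frame(tt), as.data.frame(cl))
  co$cluster_observed <- rowSums(cl) > 0
  co
}

## single patient record as a one-row data frame
make_record <- function(tt = rep(10, 9), cl = rep(0, 9), koos = 2L,
                        preop = 1L, postop = 1L, followup = 1L,
                        ni = FALSE) {
  make_cohort(1, koos = koos, preop = preop, postop = postop,
              followup = followup, ni = ni,
              tt = matrix(tt, 1, 9), cl = matrix(cl, 1, 9))[1, ]
}
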