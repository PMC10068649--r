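#' @keywords internal
"_PACKAGE"

## Shared small helpers. All randomness in the package flows through
## explicit seeds; sub-stream seeds are derived by XOR so that runs are
## reproducible and mutually independent given one root seed.

#' Derive per-run seeds from a root seed
#'
#' Run `r` uses `root_seed XOR r`, kept inside the 32-bit integer range.
#'
#' @param root_seed Integer root seed.
#' @param n Number of runs.
#' @return Integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(root_seed, n) {
  root_seed <- as.integer(root_seed)
  stopifnot(is.finite(root_seed), n >= 1)
  vapply(seq_len(n), function(r) bitwXor(root_seed, r) %% .Machine$integer.max,
         integer(1))
}

#' Clamp numeric values into an interval
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Largest-remainder apportionment of expected counts
#'
#' Turns a vector of (possibly fractional) expected counts into integers
#' summing to `round(sum(raw))`, assigning the leftover units to the cells
#' with the largest fractional parts. Used by quota sampling to reproduce
#' exact cohort marginals.
#'
#' @keywords internal
quota_counts <- function(raw) {
  counts <- floor(raw)
  short <- round(sum(raw)) - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  as.integer(counts)
}
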