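# Independent oracles for the Wasserstein distance.

# Exact transport cost via the CDF characterization: both empirical CDFs
# are piecewise constant, so the integral of |F_a - F_b| is a finite sum
# over the merged support breakpoints. Independent of the quantile-merge
# algorithm used by the package.
wd_cdf_oracle <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  if (length(xs) == 1L) return(0)
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    fa <- mean(a <= xs[i])
    fb <- mean(b <= xs[i])
    total <- total + abs(fa - fb) * (xs[i + 1L] - xs[i])
  }
  total
}

# Exhaustive minimum-cost perfect matching for equal-size multisets
# (mass 1/n each): brute force over all permutations, n <= 6.
wd_matching_oracle <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 6L)
  n <- length(a)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) mean(abs(a - b[p])), numeric(1)))
}
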