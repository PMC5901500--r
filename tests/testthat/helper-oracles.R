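# Independent brute-force oracles for the rank tests and the HWE exact test.
# These deliberately use different enumeration routes from the package
# implementation (label-vector filtering / bitmask subsets / probability
# recurrence vs. partition recursion / combn / direct log-factorials).

# Kruskal-Wallis exact p by enumerating every group-label vector and keeping
# those with the observed group sizes
kw_enum_oracle <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  k <- length(sizes)
  n <- length(values)
  labs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- apply(labs, 1L, function(l) all(tabulate(l, k) == sizes))
  labs <- labs[keep, , drop = FALSE]
  h_obs <- kw_statistic(values, rep(seq_len(k), sizes))
  h_all <- apply(labs, 1L, function(l) kw_statistic(values, l))
  mean(h_all >= h_obs - 1e-9)
}

# Wilcoxon rank-sum exact two-sided p (tail doubling) by enumerating all
# 2^n subsets and keeping those of size n_a
wrs_enum_oracle <- function(a, b) {
  n_a <- length(a)
  n <- n_a + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n_a)])
  sel <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sel <- sel[rowSums(sel) == n_a, , drop = FALSE]
  w_all <- as.vector(sel %*% ranks)
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

# HWE exact p via the heterozygote-count probability recurrence
# P(h + 2) / P(h) = (nA - h) (nB - h) / ((h + 1) (h + 2)), normalised
hwe_recurrence_oracle <- function(nAA, nAB, nBB) {
  n_a <- 2 * nAA + nAB
  n_b <- 2 * nBB + nAB
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  w <- numeric(length(h))
  w[1] <- 1
  if (length(h) > 1) {
    for (i in seq_len(length(h) - 1)) {
      hh <- h[i]
      w[i + 1] <- w[i] * (n_a - hh) * (n_b - hh) / ((hh + 1) * (hh + 2))
    }
  }
  probs <- w / sum(w)
  obs <- probs[h == nAB]
  sum(probs[probs <= obs * (1 + 1e-9)])
}
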