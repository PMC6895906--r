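# Independent oracles, deliberately written by routes different from the
# package implementation: hand formulas, exhaustive enumeration, brute-force
# counting.

# Pearson chi-square by the hand formula Sum (O - E)^2 / E over the 4 cells.
chi2_hand <- function(a, b, cc, d) {
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}

# Two-tailed Fisher exact p by exhaustive enumeration of the overlap support,
# with probabilities from binomial coefficients (not dhyper).
fet_enum <- function(k, K, m, N) {
  support <- max(0, K + m - N):min(K, m)
  pr <- choose(m, support) * choose(N - m, K - support) / choose(N, K)
  obs <- pr[support == k]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Asymmetric binary distance by explicit position-by-position counting.
bin_dist_brute <- function(x, y) {
  a <- 0; b <- 0; cc <- 0
  for (i in seq_along(x)) {
    xi <- x[i] != 0; yi <- y[i] != 0
    if (xi && yi) a <- a + 1
    else if (xi) b <- b + 1
    else if (yi) cc <- cc + 1
  }
  if (a + b + cc == 0) NA_real_ else (b + cc) / (a + b + cc)
}

# Build two gene sets realizing a given 2x2 membership table (a = shared,
# b = only A, cc = only B, d = neither) over a synthetic universe.
sets_from_table <- function(a, b, cc, d) {
  universe <- sprintf("u%03d", seq_len(a + b + cc + d))
  list(
    A = universe[seq_len(a + b)],
    B = universe[c(seq_len(a), a + b + seq_len(cc))],
    universe = universe
  )
}
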