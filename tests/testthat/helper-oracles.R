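# Independent brute-force oracles used to check the package's statistics.
# These are deliberately written from the textbook definitions, not by
# calling the implementation under test.

# step-up BH from the definition: adj_i = min_{j >= i} m * p_(j) / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided rank-sum p from the full permutation distribution,
# computed by a count-by-(subset size, rank sum) dynamic program over
# doubled midranks (a distinct mechanism from the implementation's combn)
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r2 <- as.integer(round(2 * rank(c(x, y))))   # doubled midranks: integers
  w2 <- sum(r2[seq_len(nx)])
  e2 <- nx * mean(r2)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  # counts[j + 1, s + 1] = number of size-j subsets with doubled-rank sum s
  counts <- matrix(0, nx + 1, smax + 1)
  counts[1, 1] <- 1
  for (item in r2) {
    for (j in nx:1) {
      shifted <- c(rep(0, item), counts[j, seq_len(smax + 1 - item)])
      counts[j + 1, ] <- counts[j + 1, ] + shifted
    }
  }
  sums <- 0:smax
  extreme <- abs(sums - e2) >= abs(w2 - e2) - 1e-9
  sum(counts[nx + 1, extreme]) / sum(counts[nx + 1, ])
}

# upper-tail hypergeometric from binomial coefficients
oracle_hyper_p <- function(overlap, n_annot, n_universe, n_hits) {
  js <- overlap:min(n_annot, n_hits)
  sum(choose(n_annot, js) * choose(n_universe - n_annot, n_hits - js)) /
    choose(n_universe, n_hits)
}

# hand percentile by linear interpolation between order statistics
oracle_pctl <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h)
  unname(x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo]))
}
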