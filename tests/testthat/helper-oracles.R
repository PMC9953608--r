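# Independent brute-force oracles, kept deliberately naive: combinatorial
# ratios via choose(), full enumeration, label permutation.

# two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins, summing probabilities <= that of the observed table
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  xs <- max(0, k - r2):min(k, r1)
  prob <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by direct combinatorial summation
hyper_enum_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# pick one element even from a length-one vector
pick1 <- function(x) x[sample.int(length(x), 1)]

# random 2x2 table with positive row margins and total <= n_max
rand_table <- function(n_max = 60) {
  n_tot <- pick1(4:n_max)
  r1 <- pick1(1:(n_tot - 1))
  k <- pick1(0:n_tot)
  a <- pick1(max(0, k - (n_tot - r1)):min(k, r1))
  c(a = a, b = r1 - a, c = k - a, d = n_tot - r1 - (k - a))
}

# two-sided permutation rank-sum test: shuffles group labels and compares the
# centred rank-sum statistic of group 1
ranksum_perm_oracle <- function(x, y, n_perm = 10000, seed = 42) {
  set.seed(seed)
  pooled <- c(x, y)
  n1 <- length(x)
  stat <- function(idx) {
    r <- rank(pooled)
    abs(sum(r[idx]) - n1 * (length(pooled) + 1) / 2)
  }
  obs <- stat(seq_len(n1))
  perm <- replicate(n_perm, stat(sample(length(pooled), n1)))
  mean(perm >= obs - 1e-9)
}
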