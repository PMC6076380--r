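# Independent brute-force oracles used across the suite. These stay
# deliberately naive (full enumeration) and are only run at tiny sizes.

# maxima of the running sum over all choose(m, l) hit arrangements
brute_maxima <- function(m, l) {
  combs <- utils::combn(m, l)
  apply(combs, 2L, function(pos) {
    steps <- rep(-l, m)
    steps[pos] <- m - l
    max(cumsum(steps))
  })
}

# exact two-tailed rank-sum p by enumeration of all group labelings,
# same twice-the-smaller-tail convention as the implementation
brute_wilcoxon_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  sums <- apply(utils::combn(n, n1), 2L, function(idx) sum(r[idx]))
  w <- sum(r[seq_len(n1)])
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= w + eps), mean(sums >= w - eps)))
}

# independent Benjamini-Hochberg step-up (direct definition)
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# a small planted cohort used by several tests
small_sim <- function(seed = 3, ...) {
  simulate_cohort(synth_config(n_mirnas = 120, n_cases = 12,
                               n_controls = 40, frac_de = 0.15,
                               effect_size_d = 2, seed = seed, ...))
}
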