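# Independent brute-force oracles used to validate the statistical
# primitives. Deliberately naive implementations.

# O(m^2) step-up BH: for each p, the minimum of p_j * m / rank_j over all
# j whose rank is at least p's own rank.
oracle_bh <- function(p) {
  m <- length(p)
  rk <- rank(p, ties.method = "first")
  scaled <- p * m / rk
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(scaled[rk >= rk[i]]))
  }
  q
}

# Two-sided Fisher p by direct enumeration over the hypergeometric
# support, with table probabilities from binomial coefficients.
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; tot <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(tot, c1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Log-rank chi-square computed from first principles (events before
# censorings at tied times).
oracle_logrank_chisq <- function(time, event, grp) {
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    if (n < 2) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

# Permutation p-value of the log-rank test using the oracle statistic
# (add-one estimator, Davison & Hinkley).
oracle_logrank_permutation <- function(time, event, grp, n_perm = 20000,
                                       seed = 7) {
  obs <- oracle_logrank_chisq(time, event, grp)
  withr::with_seed(seed, {
    hits <- 0
    for (i in seq_len(n_perm)) {
      stat <- oracle_logrank_chisq(time, event, sample(grp))
      if (stat >= obs - 1e-12) hits <- hits + 1
    }
    (hits + 1) / (n_perm + 1)
  })
}

# Upper-tail hypergeometric probability by direct pmf summation.
oracle_hyper_tail <- function(observed, set_size, band_size, universe) {
  ks <- observed:min(set_size, band_size)
  sum(exp(lchoose(band_size, ks) +
            lchoose(universe - band_size, set_size - ks) -
            lchoose(universe, set_size)))
}
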