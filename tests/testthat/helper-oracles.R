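# Independent brute-force oracles, deliberately coded without reference to
# the package internals they are used to check.

# Explicit Cox partial likelihood for untied data (Breslow and Efron agree):
# sum over events of [eta_i - log(sum of exp(eta_j) over subjects still at
# risk at t_i)].
brute_partial_loglik <- function(beta, time, event, x) {
  eta <- as.numeric(x) * beta
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# 1-D maximizer of the explicit partial likelihood by golden-section search.
brute_cox_beta <- function(time, event, x, interval = c(-8, 8)) {
  optimize(function(b) brute_partial_loglik(b, time, event, x),
           interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Two-group log-rank via explicit 2x2 tables with hypergeometric moments at
# every distinct event time.
brute_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(at_risk & time == t & event == 1)
    d1 <- sum(at_risk & g == 1 & time == t & event == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Benjamini-Hochberg step-up written as explicit loops.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in m:1) {
    val <- m * p[ord[i]] / i
    if (i < m) val <- min(val, q_sorted[i + 1])
    q_sorted[i] <- min(val, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Linear-interpolation sample quantile by explicit sort-and-index.
brute_quantile <- function(x, prob) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * prob
  lo <- floor(h)
  xs[lo + 1] + (h - lo) * (xs[min(lo + 2, n)] - xs[lo + 1])
}

# All permutations of 1..n (for exhaustive permutation enumeration).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}
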