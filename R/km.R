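#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times.
#' @param event event indicator (1 = death, 0 = censored).
#' @return object of class `km_estimate`: data frame with one row per
#'   distinct event time (`time`, `n_risk`, `n_event`, `survival`), where
#'   `survival` is the product-limit estimate just after that time.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) input_error("empty input")
  if (any(time <= 0)) input_error("times must be strictly positive")
  event <- as.integer(event)
  ut <- sort(unique(time[event == 1L]))
  n_risk <- vapply(ut, function(t) sum(time >= t), integer(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_estimate", "data.frame"))
}

#' Survival probability at given times from a KM estimate
#'
#' Step-function lookup: S(t) is the product-limit estimate at the largest
#' event time `<= t` (1 before the first event).
#'
#' @param km a `km_estimate`.
#' @param t numeric times.
#' @return numeric survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$time <= ti)
    if (length(idx) == 0L) 1.0 else km$survival[max(idx)]
  }, numeric(1))
}

#' Log-rank (Mantel-Haenszel) test for equal survival functions
#'
#' Observed-minus-expected test with hypergeometric variance across the
#' distinct event times, generalized to K groups; the statistic is compared
#' to a chi-square with K - 1 degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param group group labels (>= 2 groups, each with >= 1 subject).
#' @return list with `statistic`, `df`, `p`, and the per-group
#'   observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) input_error("log-rank test requires at least two groups")
  event <- as.integer(event)
  ut <- sort(unique(time[event == 1L]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k - 1L, k - 1L)
  gi <- as.integer(group)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(at_risk & time == t & event == 1L)
    nj <- vapply(seq_len(k), function(j) sum(at_risk & gi == j), numeric(1))
    dj <- vapply(seq_len(k), function(j)
      sum(at_risk & gi == j & time == t & event == 1L), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      fac <- d * (n - d) / (n - 1)
      for (a in seq_len(k - 1L)) for (b in seq_len(k - 1L)) {
        V[a, b] <- V[a, b] +
          fac * (nj[a] * ((a == b) * n - nj[b])) / n^2
      }
    }
  }
  z <- (O - E)[seq_len(k - 1L)]
  stat <- if (all(V == 0)) 0 else as.numeric(t(z) %*% solve(V, z))
  list(statistic = stat, df = k - 1L,
       p = pchisq(stat, df = k - 1L, lower.tail = FALSE),
       table = data.frame(group = levels(group), n = as.integer(table(group)),
                          observed = O, expected = E))
}
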