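# Independent oracles used across tests.

# Adjusted Rand index by brute-force pair counting.
pair_count_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_r <- sum(choose(rowSums(tab), 2))
  sum_c <- sum(choose(colSums(tab), 2))
  expected <- sum_r * sum_c / choose(n, 2)
  (sum_ij - expected) / ((sum_r + sum_c) / 2 - expected)
}

# Brute-force numeric inversion of a Hill curve by bisection on a dose grid
# (independent of the analytic inverse in the package).
grid_hill_inverse <- function(curve, effect, lo = 1e-9, hi = 1e9, tol = 1e-10) {
  f <- function(d) 100 * (1 - (curve$floor +
    (curve$ceiling - curve$floor) / (1 + (d / curve$ic50)^curve$slope))) - effect
  if (f(hi) < 0) return(Inf)
  if (f(lo) > 0) return(0)
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Closed-form Welch t statistic and two-sided p (hand formula).
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Step-up BH by direct application of the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q_sorted[i] <- min(1, min(m * p[o][j] / j))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
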