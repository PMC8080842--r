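# Independent oracles, deliberately written from first principles so they
# share no code path with the package implementations they check.

# OLS of y on x via explicit normal equations, with the slope t-test.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  XtX <- t(X) %*% X
  coefs <- solve(XtX, t(X) %*% y)
  fitted <- X %*% coefs
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  se <- sqrt(rss / (n - 2) * solve(XtX)[2, 2])
  t <- coefs[2] / se
  list(intercept = coefs[1], slope = coefs[2],
       r_squared = 1 - rss / tss,
       p_value = 2 * pt(-abs(t), df = n - 2))
}

# Benjamini-Hochberg step-up by the definition: for each i (ascending),
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, back in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- ps[i:m] * m / (i:m)
    q[i] <- min(1, min(cand))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher p-value by hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed that of the observed table.
fisher_p_oracle <- function(a, b, c, d) {
  m1 <- a + b   # list size
  n1 <- a + c   # category size
  N <- a + b + c + d
  lo <- max(0, n1 - (N - m1))
  hi <- min(m1, n1)
  ks <- lo:hi
  probs <- dhyper(ks, m1, N - m1, n1)
  p_obs <- dhyper(a, m1, N - m1, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sample KS statistic by direct ECDF enumeration over pooled values.
ks_stat_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# Brute-force sliding-window mean by explicit membership testing.
window_mean_oracle <- function(ages, values, half_width = 5) {
  vapply(seq_along(ages), function(i)
    mean(values[abs(ages - ages[i]) <= half_width]), numeric(1))
}
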