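# Independent oracles, written naively and kept separate from the package
# implementations they check.

# Brute-force ReliefF: explicit loops, no shared code with relieff_weights().
brute_force_relieff <- function(x, y, k) {
  x <- as.matrix(x)
  y <- factor(y)
  n <- nrow(x)
  p <- ncol(x)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  xn <- x
  for (j in seq_len(p)) {
    r <- maxs[j] - mins[j]
    xn[, j] <- if (r > 0) (x[, j] - mins[j]) / r else 0
  }
  priors <- table(y) / n
  w <- rep(0, p)
  for (i in seq_len(n)) {
    d <- rep(NA_real_, n)
    for (m in seq_len(n)) d[m] <- sum(abs(xn[i, ] - xn[m, ]))
    same <- setdiff(which(y == y[i]), i)
    other <- which(y != y[i])
    hits <- same[order(d[same])][1:k]
    misses <- other[order(d[other])][1:k]
    other_class <- setdiff(levels(y), as.character(y[i]))
    coef <- as.numeric(priors[other_class]) /
      (1 - as.numeric(priors[as.character(y[i])]))
    for (j in seq_len(p)) {
      for (h in hits) w[j] <- w[j] - abs(xn[i, j] - xn[h, j]) / (n * k)
      for (m in misses) w[j] <- w[j] + coef * abs(xn[i, j] - xn[m, j]) / (n * k)
    }
  }
  w
}

# Smallest k with sum_{i<=k} dbinom(i; n, 1/c) >= 1 - alpha, divided by n.
exact_chance_oracle <- function(n, alpha = 0.05, n_classes = 2) {
  cdf <- cumsum(stats::dbinom(0:n, n, 1 / n_classes))
  k <- which(cdf >= 1 - alpha)[1] - 1
  k / n
}

# Plain covariance / sd ratio, written out from first principles.
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) / (n - 1) /
    (sqrt(sum((x - mx)^2) / (n - 1)) * sqrt(sum((y - my)^2) / (n - 1)))
}
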