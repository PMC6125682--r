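# Independent brute-force oracles, deliberately naive: direct formulas only,
# no shared code with the implementation.

# Benjamini-Hochberg step-up by the textbook definition
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce step-up monotonicity from the largest rank down
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Sequential (Type I) ANOVA p-values by explicit nested normal-equations fits
seq_anova_bruteforce <- function(y, x1, x2) {
  fit_rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  n <- length(y)
  X0 <- matrix(1, n, 1)
  X1 <- cbind(X0, x1)
  X2 <- cbind(X1, x2)
  X3 <- cbind(X2, x1 * x2)
  rss <- c(fit_rss(X0), fit_rss(X1), fit_rss(X2), fit_rss(X3))
  ss_term <- -diff(rss)           # one df each
  mse <- rss[4] / (n - 4)
  f <- ss_term / mse
  stats::pf(f, 1, n - 4, lower.tail = FALSE)
}

# Upper binomial tail by exhaustive summation of exact terms
binom_tail_bruteforce <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j), 0))
}

# Spearman rho via the rank formula with average ranks
spearman_bruteforce <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small additive probe matrix for summarization tests
additive_matrix <- function(r, c) outer(r, c, `+`)
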