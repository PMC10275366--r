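# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulation of each statistic so they stay
# independent of the package's implementation paths.

# Cliff's delta by full pairwise enumeration
brute_cliffs_delta <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# Mann-Whitney U (mid-rank ties) by enumeration
brute_mwu <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Benjamini-Hochberg step-up from the closed form
# q_(i) = min_{j >= i} p_(j) * m / j, clipped at 1
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# First-component PLS1 by direct NIPALS on centered/scaled data
nipals_pls1 <- function(Xs, yc, iters = 500L, tol = 1e-12) {
  u <- yc
  w <- drop(crossprod(Xs, u)); w <- w / sqrt(sum(w^2))
  for (i in seq_len(iters)) {
    t <- drop(Xs %*% w)
    q <- sum(yc * t) / sum(t^2)
    u <- yc * q
    w_new <- drop(crossprod(Xs, u)); w_new <- w_new / sqrt(sum(w_new^2))
    if (sum((w_new - w)^2) < tol) { w <- w_new; break }
    w <- w_new
  }
  list(w = w, t = drop(Xs %*% w))
}

# two-pass Pearson correlation, scalar
brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman via the classical no-ties formula (only valid without ties)
brute_spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}

# brute-force degree recount of a network from its edge list
brute_degrees <- function(net) {
  deg <- stats::setNames(integer(nrow(net$nodes)), net$nodes$name)
  if (nrow(net$edges)) {
    for (k in seq_len(nrow(net$edges))) {
      deg[net$edges$from[k]] <- deg[net$edges$from[k]] + 1L
      deg[net$edges$to[k]] <- deg[net$edges$to[k]] + 1L
    }
  }
  deg
}
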