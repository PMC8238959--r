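# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take the dumbest correct route (rectangle membership
# scans, pairwise loops, exhaustive enumeration, closed-form step-up) and
# share no code with the package internals.

oracle_aoi <- function(array, x, y) {
  vapply(seq_along(x), function(i) {
    hit <- which(array$aois$left <= x[i] & x[i] < array$aois$right &
                   array$aois$top <= y[i] & y[i] < array$aois$bottom)
    if (length(hit) == 1L) array$aois$serial_index[hit] else NA_integer_
  }, integer(1))
}

oracle_perseverations <- function(s) {
  count <- 0L
  for (i in seq_along(s)[-1]) if (s[i] == s[i - 1]) count <- count + 1L
  count
}

oracle_regressions <- function(s) {
  count <- 0L
  for (i in seq_along(s)[-1]) {
    if (s[i] < s[i - 1] && s[i] %in% s[seq_len(i - 1)]) count <- count + 1L
  }
  count
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all choose(n1+n2, n1)
# assignments of the pooled (untied) values to the first sample.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">"))
  })
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  min(1, 2 * min(lower, upper))
}

oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(X2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

# Partial correlation via precision-matrix inversion (independent of the
# two-stage residualisation route the package uses).
oracle_partial_r <- function(x, y, Z) {
  R <- stats::cor(cbind(x, y, Z))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}
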