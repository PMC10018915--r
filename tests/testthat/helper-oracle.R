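# Independent pure-R oracles for differential testing. These deliberately do
# not call the package's scoring internals: integer log2 is computed from
# floor(log2()) with an exactness correction, and the DP is an exhaustive
# O(n^2) evaluation of every (i, j) pair.

oracle_ilog2 <- function(d) {
  f <- floor(log2(d))
  f <- f - as.integer(2^f > d) + as.integer(2^(f + 1L) <= d)
  as.integer(f)
}

# Exhaustive chaining DP: for each anchor j evaluate every eligible
# predecessor, take the maximum candidate, break ties toward the NEAREST
# (largest index) predecessor. Returns S, P (1-based, 0 = start), V.
oracle_dp <- function(set, p = map_params()) {
  a <- set$anchors
  n <- nrow(a)
  S <- a$w
  P <- integer(n)
  V <- integer(n)
  avg <- mean(a$w)
  for (j in seq_len(n)) {
    lo <- max(1L, j - p$max_range)
    if (j > lo) {
      is <- lo:(j - 1L)
      dr <- a$x[j] - a$x[is]
      dq <- a$y[j] - a$y[is]
      dd <- abs(dr - dq)
      ok <- dr > 0L & dq > 0L & dq <= p$max_dist_y & dr <= p$max_dist_x &
        dd <= p$bandwidth
      if (any(ok)) {
        m <- pmin(dq[ok], dr[ok], a$w[j])
        pen <- as.integer(trunc(dd[ok] * 0.01 * avg))
        pos <- dd[ok] > 0L
        pen[pos] <- pen[pos] + oracle_ilog2(dd[ok][pos]) %/% 2L
        cand <- S[is[ok]] + m - pen
        best <- max(cand)
        if (best > S[j]) {
          S[j] <- best
          P[j] <- max(is[ok][cand == best])
        }
      }
    }
    V[j] <- if (P[j] > 0L && V[P[j]] > S[j]) V[P[j]] else S[j]
  }
  list(S = as.integer(S), P = P, V = as.integer(V))
}

# Successor ranges computed independently of the probe ladder: on x sorted
# non-decreasing, the linear-scan answer for anchor i is the last index whose
# reference gap fits the threshold (found here by findInterval), capped at
# max_range successors. Returns 1-based exclusive upper bounds.
oracle_successor_ranges <- function(set, p = map_params()) {
  x <- set$anchors$x
  n <- length(x)
  if (n == 0L) return(integer(0))
  last <- findInterval(x + p$max_dist_x, x)      # rightmost j: x[j] <= x[i]+mdx
  as.integer(pmin(last, seq_len(n) + p$max_range) + 1L)
}

# The same by a literal per-anchor walk; used to cross-check the vectorized
# oracle on small sets.
oracle_successor_ranges_slow <- function(set, p = map_params()) {
  x <- set$anchors$x
  n <- length(x)
  vapply(seq_len(n), function(i) {
    e <- i
    while (e < n && e - i < p$max_range && x[e + 1L] - x[i] <= p$max_dist_x)
      e <- e + 1L
    e + 1L
  }, integer(1))
}

# V recomputed by explicitly walking each anchor's backtrack path.
oracle_v_by_path <- function(S, P) {
  n <- length(S)
  V <- integer(n)
  for (i in seq_len(n)) {
    m <- S[i]
    cur <- i
    while (P[cur] > 0L) {
      cur <- P[cur]
      if (S[cur] > m) m <- S[cur]
    }
    V[i] <- m
  }
  V
}

expect_same_state <- function(st1, st2, label = "") {
  expect_identical(st1$S, st2$S, label = paste(label, "S"))
  expect_identical(st1$P, st2$P, label = paste(label, "P"))
  expect_identical(st1$V, st2$V, label = paste(label, "V"))
}
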