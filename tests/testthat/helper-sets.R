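# Deterministic anchor-set generators spanning the regimes the chaining DP
# sees: sparse uniform noise, dense windows where every anchor is in range of
# every other, tie-rich coarse grids with duplicated coordinates/diagonals,
# planted collinear runs in noise, and mixed anchor spans.

gen_sparse_set <- function(n, seed, w = 15L) {
  set.seed(seed)
  lim <- max(20L * n, 1000L)
  anchor_set(anchors(w - 1L + sample.int(lim, n, replace = TRUE),
                     w - 1L + sample.int(lim, n, replace = TRUE), w))
}

gen_dense_set <- function(n, seed, w = 15L) {
  set.seed(seed)
  anchor_set(anchors(w - 1L + sample.int(3000L, n, replace = TRUE),
                     w - 1L + sample.int(3000L, n, replace = TRUE), w))
}

# coarse grid: many exact duplicates and repeated diagonals => score ties
gen_tie_set <- function(n, seed, w = 15L) {
  set.seed(seed)
  g <- max(8L, as.integer(ceiling(sqrt(n) / 2)))
  anchor_set(anchors(w - 1L + 50L * sample.int(g, n, replace = TRUE),
                     w - 1L + 50L * sample.int(g, n, replace = TRUE), w))
}

gen_planted_set <- function(n, seed) {
  cl <- max(2L, min(40L, n %/% 4L))
  nc <- max(1L, min(3L, n %/% (2L * cl)))
  noise <- max(0L, n - nc * cl)
  plant_chains(n_chains = nc, chain_len = cl, gap_mean = 100L,
               gap_jitter = 20L, noise_anchors = noise,
               read_length = as.integer(nc) * (cl * 150L + 200L),
               seed = seed)$set
}

gen_mixed_span_set <- function(n, seed) {
  set.seed(seed)
  w <- sample(11:23, n, replace = TRUE)
  lim <- max(10L * n, 1000L)
  a <- anchors(max(w) - 1L + sample.int(lim, n, replace = TRUE),
               max(w) - 1L + sample.int(lim, n, replace = TRUE), w)
  anchor_set(a)
}

# A suite of `count` deterministic sets cycling through the generators, with
# sizes drawn from `size_pool`.
gen_suite <- function(count, size_pool, seed) {
  set.seed(seed)
  sizes <- sample(size_pool, count, replace = TRUE)
  gens <- list(gen_sparse_set, gen_dense_set, gen_tie_set,
               gen_planted_set, gen_mixed_span_set)
  lapply(seq_len(count), function(i) {
    g <- gens[[(i - 1L) %% length(gens) + 1L]]
    g(max(1L, sizes[i]), seed = seed + i)
  })
}

# Fixture in which the finite-MAX_SKIP scan provably misses the best
# predecessor: a 10-anchor diagonal chain ends at F = (1000, 1000) with
# S[F] = 150; six duplicate decoys at (1200, 1900) are unchainable from F
# (gap difference 700 > bandwidth) and from each other (zero reference gap),
# and each offers the final anchor j = (1700, 2050) a negative candidate;
# F offers +109. Scanning back from j, five consecutive non-improving decoys
# exhaust max_skip = 5 before F is reached.
skip_fixture <- function() {
  anchor_set(anchors(c(seq(100L, 1000L, 100L), rep(1200L, 6L), 1700L),
                     c(seq(100L, 1000L, 100L), rep(1900L, 6L), 2050L), 15L))
}
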