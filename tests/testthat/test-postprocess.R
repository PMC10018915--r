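test_that("backtrack extracts chains, honors thresholds, reuses no anchor", {
  p <- map_params()
  s3 <- anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15))
  st <- chain_backward(s3, p)
  ch <- backtrack(st, s3, p)
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$score, 45L)
  expect_identical(ch$anchor_indices[[1]], 1:3)
  expect_identical(ch$q_start, 101L)
  expect_identical(ch$q_end, 316L)

  none <- backtrack(st, s3, map_params(min_score = 50))
  expect_identical(nrow(none), 0L)

  # two planted disjoint runs come back as two chains with disjoint anchors
  sim <- plant_chains(n_chains = 2, chain_len = 10, noise_anchors = 0,
                      read_length = 4000, seed = 31)
  st2 <- chain_forward(sim$set, p)
  ch2 <- backtrack(st2, sim$set, p)
  expect_identical(nrow(ch2), 2L)
  idx <- unlist(ch2$anchor_indices)
  expect_identical(anyDuplicated(idx), 0L)
  expect_setequal(idx, unlist(sim$truth))
})

test_that("chains truncated at a used anchor score the unshared suffix", {
  # two chain ends share the prefix 1 -> 2: the weaker end is cut where it
  # meets the consumed prefix and scores only its suffix
  s <- anchor_set(anchors(c(115, 215, 315, 415), c(115, 215, 315, 415), 15))
  st <- structure(list(S = c(15L, 30L, 45L, 44L), P = c(0L, 1L, 2L, 2L),
                       V = c(15L, 30L, 45L, 44L), n = 4L),
                  class = "chain_state")
  ch <- backtrack(st, s, map_params(min_cnt = 1, min_score = 5))
  expect_identical(nrow(ch), 2L)
  expect_identical(ch$anchor_indices[[1]], 1:3)
  expect_identical(ch$score[2], 44L - 30L)      # S[end] - S[truncation point]
  expect_identical(ch$anchor_indices[[2]], 4L)
  expect_identical(anyDuplicated(unlist(ch$anchor_indices)), 0L)

  # with min_cnt = 3 the truncated single-anchor chain is dropped, but its
  # anchor stays consumed (no third pass re-uses it)
  ch2 <- backtrack(st, s, map_params(min_cnt = 3, min_score = 5))
  expect_identical(nrow(ch2), 1L)
  expect_identical(ch2$anchor_indices[[1]], 1:3)
})

test_that("primary identification masks query-overlapping weaker chains", {
  p <- map_params()
  one <- data.frame(score = 100L, n_anchors = 12L, q_start = 0L, q_end = 200L,
                    r_start = 0L, r_end = 200L, rid = 0L, strand = "+",
                    sum_span = 180L, anchor_indices = I(list(1:12)))
  r1 <- identify_primary(one, p)
  expect_true(r1$is_primary)
  expect_identical(r1$mapq, mapping_quality(100, 0, 12))

  two <- rbind(one, data.frame(score = 80L, n_anchors = 10L, q_start = 300L,
                               q_end = 500L, r_start = 300L, r_end = 500L,
                               rid = 0L, strand = "+", sum_span = 150L,
                               anchor_indices = I(list(13:22))))
  r2 <- identify_primary(two, p)
  expect_identical(r2$is_primary, c(TRUE, TRUE))  # disjoint query intervals

  shadow <- two
  shadow$q_start[2] <- 0L
  shadow$q_end[2] <- 200L
  r3 <- identify_primary(shadow, p)
  expect_identical(r3$is_primary, c(TRUE, FALSE))
  expect_identical(r3$f2, c(80L, 100L))
  expect_identical(r3$mapq[1], mapping_quality(100, 80, 12))
  expect_identical(r3$mapq[2], 0L)
})

test_that("mapping quality follows the empirical formula and its bounds", {
  expect_identical(mapping_quality(100, 100, 20), 0L)
  expect_identical(mapping_quality(45, 0, 12), 60L)
  expect_identical(mapping_quality(45, 0, 12),
                   as.integer(min(60, round(40 * log(45)))))
  f2s <- seq(0L, 80L, 10L)
  q <- vapply(f2s, function(f2) mapping_quality(80, f2, 8), integer(1))
  expect_true(all(diff(q) <= 0L))
  expect_true(all(q >= 0L & q <= 60L))
  expect_error(mapping_quality(0, 0, 5), "f1")
  expect_error(mapping_quality(50, 60, 5), "f2")
})
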